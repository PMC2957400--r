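#' Number of polymorphic residue variant groups per core position
#'
#' @param x a [GroupCatalog-class] or an object carrying one.
#' @return integer vector of length 9: Ng(i) for i = 1..9 (the invariant
#'   l = 0 group is not counted).
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname nGroups
setMethod("nGroups", "GroupCatalog",
          function(x) vapply(x@groups, length, integer(1)))

#' @rdname nGroups
setMethod("nGroups", "ModelParams", function(x) nGroups(x@catalog))

#' Training panel allotype names
#' @param x a [GroupCatalog-class].
#' @return character vector.
#' @export
setGeneric("panelNames", function(x) standardGeneric("panelNames"))

#' @rdname panelNames
setMethod("panelNames", "GroupCatalog", function(x) x@panel)

#' Contact pairs of a catalog or contact map
#' @param x a [ContactMap-class] or [GroupCatalog-class].
#' @return data.frame with columns \code{core_pos}, \code{resno}.
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname contactPairs
setMethod("contactPairs", "ContactMap", function(x) x@pairs)

#' @rdname contactPairs
setMethod("contactPairs", "GroupCatalog", function(x) x@contacts@pairs)

#' Group membership vectors of an allotype profile
#' @param x an [AllotypeProfile-class].
#' @return list of length 9 of 0/1 vectors (index 1 is the l = 0 group).
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname membership
setMethod("membership", "AllotypeProfile", function(x) x@membership)

#' Catalog coverage of an allotype
#'
#' Fraction of the allotype's polymorphic contacting residue variation that
#' the catalog accounts for; variants outside the catalog contribute zero
#' energy to predictions.
#'
#' @param x an [AllotypeProfile-class].
#' @param level \code{"group"} (default) or \code{"residue"}.
#' @return scalar in [0, 1].
#' @export
setGeneric("coveredFraction",
           function(x, level = c("group", "residue"))
             standardGeneric("coveredFraction"))

#' @rdname coveredFraction
setMethod("coveredFraction", "AllotypeProfile",
          function(x, level = c("group", "residue")) {
            level <- match.arg(level)
            if (level == "group") x@coveredFraction else x@residueFraction
          })

#' Variants observed in an allotype but absent from the catalog
#' @param x an [AllotypeProfile-class].
#' @return data.frame (\code{core_pos}, \code{resno}, \code{type}).
#' @export
setGeneric("missingGroups", function(x) standardGeneric("missingGroups"))

#' @rdname missingGroups
setMethod("missingGroups", "AllotypeProfile", function(x) x@missingGroups)

#' Parameter matrix for one core position
#' @param x a [ModelParams-class].
#' @param position core position i in 1..9.
#' @return 20 x (Ng(i) + 1) matrix (rows: amino acids, columns l0, l1, ...).
#' @export
setGeneric("betaMatrix",
           function(x, position) standardGeneric("betaMatrix"))

#' @rdname betaMatrix
setMethod("betaMatrix", "ModelParams", function(x, position) {
  stopifnot(position %in% seq_len(N_CORE))
  x@beta[[position]]
})

#' Thermal energy kT of a model (kcal/mol)
#' @param x a [ModelParams-class].
#' @return positive scalar.
#' @export
setGeneric("thermalEnergy", function(x) standardGeneric("thermalEnergy"))

#' @rdname thermalEnergy
setMethod("thermalEnergy", "ModelParams", function(x) x@kT)

#' L1 bound t of a fitted model (kcal/mol)
#' @param x a [ModelParams-class] or [FitResult-class].
#' @return non-negative scalar (possibly \code{Inf}).
#' @export
setGeneric("l1Bound", function(x) standardGeneric("l1Bound"))

#' @rdname l1Bound
setMethod("l1Bound", "ModelParams", function(x) x@l1Bound)

#' @rdname l1Bound
setMethod("l1Bound", "FitResult", function(x) x@model@l1Bound)

#' Per-register energies of a prediction
#' @param x a [RegisterScores-class].
#' @return numeric vector named by 0-based register index.
#' @export
setGeneric("registerEnergies",
           function(x) standardGeneric("registerEnergies"))

#' @rdname registerEnergies
setMethod("registerEnergies", "RegisterScores", function(x) x@energies)

#' Normalized Boltzmann register weights of a prediction
#' @param x a [RegisterScores-class].
#' @return numeric vector summing to 1.
#' @export
setGeneric("registerWeights",
           function(x) standardGeneric("registerWeights"))

#' @rdname registerWeights
setMethod("registerWeights", "RegisterScores", function(x) x@weights)

#' Averaged binding affinity of a prediction (kcal/mol)
#' @param x a [RegisterScores-class].
#' @return scalar; higher = stronger binder.
#' @export
setGeneric("affinity", function(x) standardGeneric("affinity"))

#' @rdname affinity
setMethod("affinity", "RegisterScores", function(x) x@dG)

#' Ranked binding cores of a prediction
#' @param x a [RegisterScores-class].
#' @return data.frame (\code{M}, \code{core}, \code{dG_M}, \code{gap})
#'   sorted by decreasing register energy.
#' @export
setGeneric("rankedCores", function(x) standardGeneric("rankedCores"))

#' @rdname rankedCores
setMethod("rankedCores", "RegisterScores", function(x) x@cores)

#' Affinity records of a dataset
#' @param x a [TrainingDataset-class].
#' @return data.frame (\code{peptide_id}, \code{peptide}, \code{allele},
#'   \code{dG}).
#' @export
setGeneric("trainingRecords",
           function(x) standardGeneric("trainingRecords"))

#' @rdname trainingRecords
setMethod("trainingRecords", "TrainingDataset", function(x) x@records)

#' Fitted model of a fit result
#' @param x a [FitResult-class].
#' @return a [ModelParams-class].
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))

#' @rdname fittedModel
setMethod("fittedModel", "FitResult", function(x) x@model)

#' Achieved mean square error of a fit (kcal^2/mol^2)
#' @param x a [FitResult-class].
#' @return scalar.
#' @export
setGeneric("achievedMSE", function(x) standardGeneric("achievedMSE"))

#' @rdname achievedMSE
setMethod("achievedMSE", "FitResult", function(x) x@mse)

#' Multistart log of a fit
#' @param x a [FitResult-class].
#' @return data.frame with one row per start.
#' @export
setGeneric("startLog", function(x) standardGeneric("startLog"))

#' @rdname startLog
setMethod("startLog", "FitResult", function(x) x@startLog)
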