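N_CORE <- 9L  # core positions P1..P9 occupying the class II binding groove

#' Peptide-contacting MHC residues
#'
#' A \code{ContactMap} records which MHC chain residues (in the numbering of
#' the panel alignment) contact each of the nine peptide core positions in at
#' least one peptide-MHC complex structure. Contacts are defined by a
#' non-hydrogen interatomic separation strictly below 4 Angstrom; maps may
#' also be supplied directly as tables, decoupled from any structure.
#'
#' @slot pairs data.frame with integer columns \code{core_pos} (1-9) and
#'   \code{resno} (MHC residue number in panel alignment coordinates).
#' @slot provenance character vector of structure identifiers (or
#'   \code{"supplied"} for config-provided maps).
#' @seealso [extractContacts()], [readContactMap()]
#' @export
setClass("ContactMap",
  representation(pairs = "data.frame", provenance = "character"),
  prototype(pairs = data.frame(core_pos = integer(), resno = integer()),
            provenance = character()))

setValidity("ContactMap", function(object) {
  p <- object@pairs
  if (!all(c("core_pos", "resno") %in% names(p)))
    return("pairs must have columns core_pos and resno")
  if (nrow(p) && (any(p$core_pos < 1L) || any(p$core_pos > N_CORE)))
    return("core_pos must lie in 1..9")
  if (anyDuplicated(p)) return("duplicate contact pairs")
  TRUE
})

#' Catalog of MHC residue variant groups
#'
#' For each peptide core position P1-P9, the catalog lists groups of
#' polymorphic MHC residue variants (residue number + one-letter type) that
#' always co-occur across the training panel, merged maximally: two variants
#' share a group exactly when the sets of panel allotypes carrying them are
#' identical. Variants carried by every panel member form the implicit
#' invariant group l = 0; polymorphic groups are indexed l = 1..Ng(i). The
#' catalog defines the index space of the model parameter tensor beta[i,j,l].
#'
#' @slot groups list of length 9; element i is a list of data.frames
#'   (\code{resno}, \code{type}) giving the variants of groups l = 1..Ng(i),
#'   ordered deterministically by smallest residue number then type.
#' @slot invariant list of length 9; element i is a data.frame
#'   (\code{resno}, \code{type}) of contacting variants common to the whole
#'   panel (the l = 0 group).
#' @slot panel character, names of the training panel allotypes.
#' @slot contacts the [ContactMap-class] the catalog was built from.
#' @slot metadata list; records the residue numbering convention and build
#'   parameters.
#' @seealso [buildGroupCatalog()], [nGroups()], [profileAllotype()]
#' @export
setClass("GroupCatalog",
  representation(groups = "list", invariant = "list", panel = "character",
                 contacts = "ContactMap", metadata = "list"),
  prototype(groups = rep(list(list()), 9L),
            invariant = rep(list(data.frame(resno = integer(),
                                            type = character())), 9L),
            panel = character(), metadata = list()))

setValidity("GroupCatalog", function(object) {
  if (length(object@groups) != N_CORE) return("groups must have length 9")
  if (length(object@invariant) != N_CORE) return("invariant must have length 9")
  for (i in seq_len(N_CORE)) {
    gs <- object@groups[[i]]
    if (!is.list(gs)) return("each groups[[i]] must be a list")
    seen <- character()
    for (g in gs) {
      if (!all(c("resno", "type") %in% names(g)))
        return("each group needs resno and type columns")
      key <- paste(g$resno, g$type)
      if (any(key %in% seen))
        return(sprintf("overlapping variant sets at core position %d", i))
      seen <- c(seen, key)
    }
  }
  TRUE
})

#' Binary group membership of one MHC allotype
#'
#' Encodes an allotype for prediction: \code{z[i, l] = 1} when the allotype
#' carries every variant of group l at core position i. The invariant group
#' l = 0 is always present. Variants observed in the allotype's sequence but
#' absent from the catalog cannot be scored (their parameters are implicitly
#' zero) and are reported in \code{missingGroups} together with coverage
#' fractions, so predictions for poorly covered allotypes can be flagged.
#'
#' @slot name allotype name, e.g. \code{"DRB1*0101"}.
#' @slot membership list of length 9; element i is a 0/1 numeric vector of
#'   length Ng(i) + 1 whose first entry (l = 0) is always 1.
#' @slot coveredFraction group-level coverage in [0, 1]: matched groups over
#'   matched groups plus unmatched variants.
#' @slot residueFraction residue-level coverage in [0, 1]: contacting variant
#'   residues at polymorphic positions found in some catalog group, over all
#'   such residues.
#' @slot missingGroups data.frame (\code{core_pos}, \code{resno},
#'   \code{type}) of observed variants absent from the catalog.
#' @seealso [profileAllotype()], [coveredFraction()]
#' @export
setClass("AllotypeProfile",
  representation(name = "character", membership = "list",
                 coveredFraction = "numeric", residueFraction = "numeric",
                 missingGroups = "data.frame"),
  prototype(coveredFraction = 1, residueFraction = 1,
            missingGroups = data.frame(core_pos = integer(),
                                       resno = integer(),
                                       type = character())))

setValidity("AllotypeProfile", function(object) {
  if (length(object@membership) != N_CORE)
    return("membership must have length 9")
  for (z in object@membership) {
    if (!length(z) || z[1L] != 1)
      return("invariant group (l = 0) must be present at every position")
    if (!all(z %in% c(0, 1))) return("membership values must be 0/1")
  }
  TRUE
})

#' Fitted pan-allotype model parameters
#'
#' Holds the parameter tensor beta[i, j, l] (kcal/mol): the contribution of
#' peptide core residue type j at position Pi contacting MHC residue group l.
#' The l = 0 slice carries the contribution of invariant contacting residues.
#' kT controls the register weighting in the thermodynamic average and is
#' stored with the model because predictions depend on it.
#'
#' @slot catalog the [GroupCatalog-class] defining the index space.
#' @slot beta list of length 9; element i is a 20 x (Ng(i) + 1) matrix with
#'   amino-acid rownames and colnames \code{l0, l1, ...}.
#' @slot kT positive scalar, kcal/mol (default 0.592, RT at 298 K).
#' @slot l1Bound the L1 constraint bound t used at fitting (kcal/mol);
#'   \code{Inf} for unconstrained or imported models without a stated bound.
#' @slot trainingAllotypes names of allotypes in the training data.
#' @slot metadata list (seed, fit diagnostics, provenance).
#' @seealso [fitPanRTA()], [predictAffinity()], [betaMatrix()]
#' @export
setClass("ModelParams",
  representation(catalog = "GroupCatalog", beta = "list", kT = "numeric",
                 l1Bound = "numeric", trainingAllotypes = "character",
                 metadata = "list"),
  prototype(kT = 0.592, l1Bound = Inf, trainingAllotypes = character(),
            metadata = list()))

setValidity("ModelParams", function(object) {
  if (length(object@beta) != N_CORE) return("beta must have length 9")
  ng <- nGroups(object@catalog)
  for (i in seq_len(N_CORE)) {
    b <- object@beta[[i]]
    if (!is.matrix(b) || nrow(b) != 20L)
      return("each beta[[i]] must be a 20-row matrix")
    if (ncol(b) != ng[i] + 1L)
      return(sprintf("beta[[%d]] must have Ng(i) + 1 = %d columns", i,
                     ng[i] + 1L))
  }
  if (length(object@kT) != 1L || object@kT <= 0) return("kT must be > 0")
  if (object@l1Bound < 0) return("l1Bound must be >= 0")
  TRUE
})

#' Register-resolved prediction for one peptide-allotype pair
#'
#' @slot peptideId peptide identifier.
#' @slot allotype allotype name.
#' @slot energies numeric vector of per-register energies dG_M (kcal/mol),
#'   named by 0-based register index M = 0..L-9.
#' @slot weights normalized Boltzmann weights exp(dG_M/kT) / sum, same order.
#' @slot dG the Boltzmann-weighted average affinity (kcal/mol); higher means
#'   stronger binding.
#' @slot cores data.frame (\code{M}, \code{core}, \code{dG_M}, \code{gap})
#'   ranked by decreasing dG_M (ties: smaller M first); \code{gap} is the
#'   drop from the primary core in kcal/mol.
#' @seealso [predictAffinity()], [findCores()]
#' @export
setClass("RegisterScores",
  representation(peptideId = "character", allotype = "character",
                 energies = "numeric", weights = "numeric", dG = "numeric",
                 cores = "data.frame"))

setValidity("RegisterScores", function(object) {
  if (length(object@energies) != length(object@weights))
    return("energies and weights must have equal length")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-8)
    return("weights must sum to 1")
  TRUE
})

#' Experimental affinity records for fitting and evaluation
#'
#' @slot records data.frame with columns \code{peptide_id}, \code{peptide},
#'   \code{allele} and \code{dG} (kcal/mol; IC50 inputs are converted on
#'   load, see [ic50ToAffinity()]).
#' @slot unit unit of the original input (\code{"kcal/mol"} or
#'   \code{"ic50_nM"}).
#' @seealso [readAffinityTable()], [genDataset()]
#' @export
setClass("TrainingDataset",
  representation(records = "data.frame", unit = "character"),
  prototype(unit = "kcal/mol"))

setValidity("TrainingDataset", function(object) {
  need <- c("peptide_id", "peptide", "allele", "dG")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns",
                 paste(need, collapse = ", ")))
  TRUE
})

#' Result of an L1-constrained model fit
#'
#' @slot model the fitted [ModelParams-class].
#' @slot mse achieved mean square error (kcal^2/mol^2) at the best start.
#' @slot constraintActive TRUE when the L1 constraint is tight at the
#'   returned optimum (within solver tolerance).
#' @slot nNonzero number of nonzero beta entries at the optimum.
#' @slot startLog data.frame with one row per multistart solve (start id,
#'   bound t, objective, iterations, convergence flag).
#' @slot config the fit configuration used (see [fitConfig()]).
#' @export
setClass("FitResult",
  representation(model = "ModelParams", mse = "numeric",
                 constraintActive = "logical", nNonzero = "integer",
                 startLog = "data.frame", config = "list"))

#' Per-position binding-specificity variation for one allotype
#'
#' @slot allotype allotype name.
#' @slot contributions 9 x 20 matrix of per-residue affinity contributions
#'   dG[T, i, j] = sum_l beta[i, j, l] z[i, T, l] (kcal/mol).
#' @slot sigma length-9 vector: population standard deviation (1/20
#'   normalization) of the 20 contributions at each core position.
#' @slot range length-9 vector: max minus min contribution per position, a
#'   secondary variation statistic.
#' @seealso [specificityVariation()]
#' @export
setClass("SpecificityProfile",
  representation(allotype = "character", contributions = "matrix",
                 sigma = "numeric", range = "numeric"))
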