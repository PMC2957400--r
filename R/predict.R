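# ---- parameter index space -------------------------------------------------
# The beta tensor is flattened position-major: for core position i the block
# holds (Ng(i) + 1) groups of 20 residue coefficients, group-major, so
# flat index = offset(i) + 20 * l + j with l in 0..Ng(i), j in 1..20.

.paramOffsets <- function(catalog) {
  sizes <- 20L * (nGroups(catalog) + 1L)
  list(offsets = cumsum(c(0L, sizes[-N_CORE])), sizes = sizes,
       total = sum(sizes))
}

.flattenBeta <- function(model) {
  unlist(lapply(model@beta, as.numeric), use.names = FALSE)
}

.unflattenBeta <- function(catalog, flat) {
  ng <- nGroups(catalog)
  out <- vector("list", N_CORE)
  pos <- 0L
  for (i in seq_len(N_CORE)) {
    k <- 20L * (ng[i] + 1L)
    out[[i]] <- matrix(flat[pos + seq_len(k)], nrow = 20L,
                       dimnames = list(AA_CODES,
                                       paste0("l", 0:ng[i])))
    pos <- pos + k
  }
  out
}

.zeroBeta <- function(catalog) .unflattenBeta(catalog, numeric(.paramOffsets(catalog)$total))

.checkCompatible <- function(profile, catalog) {
  ng <- nGroups(catalog)
  zl <- vapply(profile@membership, length, integer(1))
  if (!all(zl == ng + 1L))
    stop(sprintf(
      "profile '%s' is indexed against a different catalog (group counts %s vs %s)",
      profile@name, paste(zl - 1L, collapse = ","),
      paste(ng, collapse = ",")))
  invisible(TRUE)
}

# Sparse register design. peptIdx: list of integer-encoded peptides;
# profiles: list (same length) of AllotypeProfile. Returns the (rows =
# registers, cols = parameters) 0/1 matrix plus row bookkeeping.
.registerDesign <- function(peptIdx, profiles, catalog) {
  po <- .paramOffsets(catalog)
  nreg <- vapply(peptIdx, length, integer(1)) - 8L
  rowEnd <- cumsum(nreg)
  rowStart <- rowEnd - nreg + 1L
  ii <- vector("list", length(peptIdx))
  jj <- vector("list", length(peptIdx))
  for (k in seq_along(peptIdx)) {
    idx <- peptIdx[[k]]
    R <- nreg[k]
    act <- lapply(profiles[[k]]@membership, function(z) which(z == 1) - 1L)
    # jmat[r, i]: residue column at peptide position i + (r - 1)
    jmat <- vapply(seq_len(N_CORE),
                   function(i) idx[i:(i + R - 1L)], integer(R))
    if (R == 1L) jmat <- matrix(jmat, nrow = 1L)
    rows <- cols <- vector("list", N_CORE)
    for (i in seq_len(N_CORE)) {
      li <- act[[i]]
      rows[[i]] <- rep(seq_len(R), times = length(li))
      cols[[i]] <- rep(po$offsets[i] + 20L * li, each = R) +
        rep(jmat[, i], times = length(li))
    }
    ii[[k]] <- rowStart[k] - 1L + unlist(rows, use.names = FALSE)
    jj[[k]] <- unlist(cols, use.names = FALSE)
  }
  Phi <- Matrix::sparseMatrix(i = unlist(ii, use.names = FALSE),
                              j = unlist(jj, use.names = FALSE),
                              x = 1, dims = c(rowEnd[length(rowEnd)],
                                              po$total))
  list(Phi = Phi, nreg = nreg, rowStart = rowStart,
       record = rep.int(seq_along(nreg), nreg))
}

# Per-record Boltzmann averages of register energies e (stacked by record).
# Returns dG per record, weights per row, and max-shifted intermediates for
# gradient reuse.
.boltzmannByRecord <- function(e, nreg, kT) {
  n <- length(nreg)
  maxR <- max(nreg)
  slot <- sequence(nreg)
  rec <- rep.int(seq_len(n), nreg)
  Em <- matrix(-Inf, n, maxR)
  Em[cbind(rec, slot)] <- e
  mx <- Em[, 1L]
  if (maxR > 1L)
    for (c in 2:maxR) mx <- pmax(mx, Em[, c])
  W <- exp((Em - mx) / kT)          # -Inf pads -> 0
  denom <- rowSums(W)
  Wn <- W / denom
  E0 <- Em
  E0[E0 == -Inf] <- 0
  dG <- rowSums(Wn * E0)
  list(dG = dG, w = Wn[cbind(rec, slot)], rec = rec)
}

# ---- exported operations ---------------------------------------------------

#' Boltzmann-weighted average of register energies
#'
#' dG = sum_M dG_M exp(dG_M / kT) / sum_M exp(dG_M / kT), computed with a
#' max-shift so that arbitrarily large energies do not overflow. As kT -> 0
#' the average tends to the best register; as kT -> Inf to the arithmetic
#' mean.
#'
#' @param energies non-empty numeric vector of per-register energies
#'   (kcal/mol).
#' @param kT positive scalar, kcal/mol.
#' @return list with \code{dG} (the average) and \code{weights}
#'   (normalized, summing to 1).
#' @examples
#' thermodynamicAverage(c(0, log(3)), kT = 1)  # weights 1/4, 3/4
#' @export
thermodynamicAverage <- function(energies, kT) {
  if (!length(energies)) stop("energies must be non-empty")
  if (!is.numeric(kT) || length(kT) != 1L || !is.finite(kT) || kT <= 0)
    stop("kT must be a positive finite scalar")
  m <- max(energies)
  w <- exp((energies - m) / kT)
  w <- w / sum(w)
  list(dG = sum(w * energies), weights = w)
}

#' Binding energy of a peptide in one register
#'
#' dG_M = sum_{i=1..9} sum_j sum_{l=0..Ng(i)} beta[i,j,l] x[i+M, j] z[i, l]:
#' each core position contributes its residue's coefficient summed over the
#' groups the allotype carries. Groups absent from the profile contribute
#' exactly zero.
#'
#' @param peptide peptide sequence (character) or the one-hot matrix from
#'   [encodePeptide()].
#' @param profile an [AllotypeProfile-class] indexed against the model's
#'   catalog.
#' @param model a [ModelParams-class].
#' @param M 0-based register index, 0 <= M <= L - 9 (the core occupies
#'   peptide positions M+1..M+9).
#' @return scalar energy in kcal/mol.
#' @export
registerEnergy <- function(peptide, profile, model, M) {
  idx <- if (is.matrix(peptide)) max.col(peptide) else .encodeIdx(peptide)
  L <- length(idx)
  if (!is.numeric(M) || length(M) != 1L || M != round(M))
    stop("M must be a single integer")
  if (M < 0 || M > L - 9L)
    stop(sprintf("register M = %d out of range 0..%d", M, L - 9L))
  .checkCompatible(profile, model@catalog)
  e <- 0
  for (i in seq_len(N_CORE)) {
    j <- idx[i + M]
    e <- e + sum(model@beta[[i]][j, ] * profile@membership[[i]])
  }
  e
}

#' Predict the binding affinity of a peptide to an allotype
#'
#' Scores every 9-mer register of the peptide with the linear energy model
#' and combines them by the Boltzmann-weighted average. The returned object
#' also ranks the registers as candidate binding cores (decreasing energy,
#' ties broken toward the N-terminal register).
#'
#' @inheritParams registerEnergy
#' @param peptideId identifier stored in the result.
#' @return a [RegisterScores-class].
#' @examples
#' gt <- genGroundTruth(syntheticSpec(seed = 1))
#' predictAffinity("ILKEPVHGA", gt$profiles[[1]], gt$model)
#' @export
predictAffinity <- function(peptide, profile, model, peptideId = "peptide") {
  idx <- .encodeIdx(peptide)
  .checkCompatible(profile, model@catalog)
  des <- .registerDesign(list(idx), list(profile), model@catalog)
  e <- as.numeric(des$Phi %*% .flattenBeta(model))
  ta <- thermodynamicAverage(e, model@kT)
  L <- length(idx)
  Ms <- 0:(L - 9L)
  ord <- order(-e, Ms)
  cores <- data.frame(
    M = Ms[ord],
    core = vapply(Ms[ord] + 1L,
                  function(s) substr(peptide, s, s + 8L), character(1)),
    dG_M = e[ord],
    gap = e[ord][1L] - e[ord],
    stringsAsFactors = FALSE)
  new("RegisterScores", peptideId = peptideId, allotype = profile@name,
      energies = setNames(e, Ms), weights = setNames(ta$weights, Ms),
      dG = ta$dG, cores = cores)
}

#' Identify the primary and secondary binding cores of a peptide
#'
#' Ranks the 9-mer registers by decreasing register energy. The first entry
#' is the primary core; subsequent entries are secondary cores with
#' \code{gap}, their energy drop from the primary in kcal/mol.
#'
#' @inheritParams predictAffinity
#' @param top_n number of cores to return (>= 1; truncated to the number of
#'   registers).
#' @return data.frame (\code{M}, \code{core}, \code{dG_M}, \code{gap}).
#' @export
findCores <- function(peptide, profile, model, top_n = 3L) {
  if (!is.numeric(top_n) || top_n < 1L) stop("top_n must be >= 1")
  rs <- predictAffinity(peptide, profile, model)
  head(rs@cores, top_n)
}

# Vectorized prediction of average affinities for many records; used by
# fitting, evaluation and the synthetic generator.
.batchPredict <- function(peptides, alleles, profiles, model) {
  peptIdx <- lapply(peptides, .encodeIdx)
  prof <- profiles[alleles]
  if (any(vapply(prof, is.null, logical(1))))
    stop("missing profile for allele(s): ",
         paste(unique(alleles[vapply(prof, is.null, logical(1))]),
               collapse = ", "))
  des <- .registerDesign(peptIdx, prof, model@catalog)
  e <- as.numeric(des$Phi %*% .flattenBeta(model))
  .boltzmannByRecord(e, des$nreg, model@kT)$dG
}
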