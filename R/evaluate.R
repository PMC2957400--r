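#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by the number of
#' (binder, non-binder) pairs; tied scores count 1/2, via midranks.
#'
#' @param scores numeric prediction scores (higher = more binder-like).
#' @param labels logical (or 0/1) binder labels; both classes must be
#'   present.
#' @return scalar AUC in [0, 1].
#' @export
computeAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be equal-length and complete")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L) stop("no binders (positive class) in labels")
  if (nneg == 0L) stop("no non-binders (negative class) in labels")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Root-mean-square error, correlation and mean signed difference
#'
#' The mean signed difference (predicted minus experimental) diagnoses
#' systematic affinity shifts that inflate RMSE without degrading
#' discrimination.
#'
#' @param predicted,experimental numeric vectors of affinities (kcal/mol),
#'   length >= 2, finite.
#' @param method correlation flavor: \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return list with \code{rmse}, \code{correlation} (NA with a warning if
#'   either vector has zero variance) and \code{meanDiff}.
#' @export
computeRMSECorr <- function(predicted, experimental,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(predicted) != length(experimental) || length(predicted) < 2L)
    stop("need two equal-length vectors with n >= 2")
  if (any(!is.finite(predicted)) || any(!is.finite(experimental)))
    stop("inputs must be finite")
  rmse <- sqrt(mean((predicted - experimental)^2))
  r <- if (sd(predicted) == 0 || sd(experimental) == 0) {
    warning("zero-variance input; correlation undefined")
    NA_real_
  } else cor(predicted, experimental, method = method)
  list(rmse = rmse, correlation = r,
       meanDiff = mean(predicted - experimental))
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired one-sided (or two-sided) test computed exactly: zero differences
#' are dropped, absolute differences receive midranks, and the null
#' distribution of the positive-rank sum is enumerated over all 2^n sign
#' assignments (via the equivalent rank-sum convolution, so ties are
#' handled exactly rather than by a normal approximation).
#'
#' @param a,b paired numeric vectors, 1 <= n <= 25 after removing zero
#'   differences.
#' @param alternative \code{"greater"} (a tends to exceed b; default) or
#'   \code{"two.sided"} (twice the smaller tail, capped at 1).
#' @return exact p-value.
#' @examples
#' wilcoxonSignedRankExact(c(2, 3, 4), c(1, 1, 5))
#' @export
wilcoxonSignedRankExact <- function(a, b,
                                    alternative = c("greater",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  d <- a - b
  if (anyNA(d)) stop("inputs must be complete")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no nonzero differences remain")
  if (n > 25L) stop("exact enumeration supported for n <= 25 pairs")
  r2 <- round(2 * rank(abs(d)))            # doubled midranks are integers
  wobs <- sum(r2[d > 0])
  # distribution of the doubled positive-rank sum over all sign vectors
  maxs <- sum(r2)
  f <- numeric(maxs + 1L); f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(maxs + 1L - ri)])
    f <- f + shifted
  }
  tot <- 2^n
  pGreater <- sum(f[(wobs + 1L):(maxs + 1L)]) / tot
  if (alternative == "greater") return(pGreater)
  pLess <- sum(f[seq_len(wobs + 1L)]) / tot
  min(1, 2 * min(pGreater, pLess))
}

#' Per-position binding-specificity variation of an allotype
#'
#' The contribution of residue type j at core position Pi for allotype T is
#' dG[T, i, j] = sum_l beta[i, j, l] z[i, T, l]. The specificity carried by
#' position Pi is summarized as the standard deviation of the 20
#' contributions, with population (1/20) normalization; positions with
#' large sigma act as anchor positions. Adding a constant to all 20
#' contributions at a position leaves sigma unchanged. The max-minus-min
#' range is reported as a secondary statistic.
#'
#' @param model a [ModelParams-class].
#' @param profile an [AllotypeProfile-class] compatible with the model's
#'   catalog.
#' @return a [SpecificityProfile-class].
#' @export
specificityVariation <- function(model, profile) {
  .checkCompatible(profile, model@catalog)
  contrib <- matrix(0, N_CORE, 20L,
                    dimnames = list(paste0("P", seq_len(N_CORE)), AA_CODES))
  for (i in seq_len(N_CORE))
    contrib[i, ] <- as.numeric(model@beta[[i]] %*% profile@membership[[i]])
  mu <- rowMeans(contrib)
  sigma <- sqrt(rowMeans((contrib - mu)^2))
  new("SpecificityProfile", allotype = profile@name,
      contributions = contrib, sigma = unname(sigma),
      range = unname(apply(contrib, 1L, max) - apply(contrib, 1L, min)))
}

#' Leave-one-allele-out cross-validation
#'
#' For each allotype in the dataset, fits a model on all other allotypes'
#' records and predicts the held-out allotype, estimating performance on
#' novel MHC types. Binder labels for the AUC use an IC50 cutoff
#' (default 1000 nM) converted to the affinity scale. When a held-out
#' allotype carries a group present in no training allotype, its
#' contribution to predictions is necessarily zero and a coverage warning
#' is emitted.
#'
#' @param dataset a [TrainingDataset-class] spanning >= 2 allotypes.
#' @param catalog a [GroupCatalog-class].
#' @param profiles named list of [AllotypeProfile-class] covering all
#'   alleles.
#' @param config a [fitConfig()] list used for every fold.
#' @param binderIC50 IC50 cutoff in nM defining binders (default 1000).
#' @param RT conversion constant for the cutoff (kcal/mol).
#' @param alleles which allotypes to hold out and evaluate (default: all
#'   alleles in the dataset; training always uses all other alleles).
#' @return list with \code{reports} (data.frame: allotype, auc, rmse,
#'   correlation, meanDiff, n, nBinders, binderIC50), \code{manifests}
#'   (per-fold training (peptide_id, allele) tables), \code{models}
#'   (per-fold [FitResult-class]) and \code{predictions} (per-fold
#'   data.frame of predicted and experimental affinities).
#' @export
leaveOneAlleleOut <- function(dataset, catalog, profiles,
                              config = fitConfig(), binderIC50 = 1000,
                              RT = 0.592, alleles = NULL) {
  rec <- dataset@records
  if (length(unique(rec$allele)) < 2L)
    stop("leave-one-allele-out requires records for >= 2 allotypes")
  if (is.null(alleles)) alleles <- unique(rec$allele)
  else if (!all(alleles %in% rec$allele))
    stop("requested allele(s) absent from dataset: ",
         paste(setdiff(alleles, rec$allele), collapse = ", "))
  thr <- ic50ToAffinity(binderIC50, RT)
  reports <- data.frame()
  manifests <- list(); models <- list(); predictions <- list()
  for (a in alleles) {
    testRec <- rec[rec$allele == a, , drop = FALSE]
    if (!nrow(testRec)) {
      warning(sprintf("allotype %s has no evaluable records; skipped", a))
      next
    }
    trainRec <- rec[rec$allele != a, , drop = FALSE]
    trainDs <- new("TrainingDataset", records = trainRec,
                   unit = dataset@unit)
    # coverage: groups of the held-out profile absent from all training
    trainProf <- profiles[unique(trainRec$allele)]
    uncovered <- 0L
    for (i in seq_len(N_CORE)) {
      zHeld <- profiles[[a]]@membership[[i]]
      if (length(zHeld) < 2L) next
      zTrain <- Reduce(`pmax`, lapply(trainProf, function(p)
        p@membership[[i]]))
      uncovered <- uncovered + sum(zHeld[-1L] == 1 & zTrain[-1L] == 0)
    }
    if (uncovered > 0L)
      warning(sprintf(
        "held-out allotype %s carries %d group(s) absent from all training allotypes; their contribution is zero",
        a, uncovered))
    fit <- fitPanRTA(trainDs, catalog, profiles, config)
    pred <- .batchPredict(testRec$peptide, testRec$allele, profiles,
                          fit@model)
    labels <- testRec$dG >= thr
    auc <- if (any(labels) && any(!labels))
      computeAUC(pred, labels) else NA_real_
    rc <- computeRMSECorr(pred, testRec$dG)
    reports <- rbind(reports, data.frame(
      allotype = a, auc = auc, rmse = rc$rmse,
      correlation = rc$correlation, meanDiff = rc$meanDiff,
      n = nrow(testRec), nBinders = sum(labels), binderIC50 = binderIC50,
      stringsAsFactors = FALSE))
    manifests[[a]] <- trainRec[, c("peptide_id", "allele")]
    models[[a]] <- fit
    predictions[[a]] <- data.frame(peptide_id = testRec$peptide_id,
                                   allele = a, predicted = pred,
                                   experimental = testRec$dG,
                                   stringsAsFactors = FALSE)
  }
  rownames(reports) <- NULL
  list(reports = reports, manifests = manifests, models = models,
       predictions = predictions)
}
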