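#' Configuration for model fitting
#'
#' @param l1Bound the L1 bound t (kcal/mol), or a numeric grid of bounds
#'   from which one value is drawn per start.
#' @param multistart number of random starts (>= 1; default 20).
#' @param seed integer RNG seed controlling the starts.
#' @param initializer \code{"random"} (uniform starts in
#'   \code{[-startRange, startRange]} plus one zero start),
#'   \code{"zeros"}, or \code{"svd-combined"} (additionally seeds one start
#'   from [svdInitialize()] built on per-allotype single-type fits).
#' @param startRange half-width of the uniform random start distribution
#'   (kcal/mol).
#' @param epsilon pseudoinverse tolerance for the SVD initializer;
#'   \code{NULL} means 1e-8 times the largest singular value.
#' @param gtol projected-gradient infinity-norm convergence tolerance.
#' @param maxit maximum iterations per start.
#' @param kT thermal energy for the register average (kcal/mol).
#' @param rtaMultistart starts used for the inner single-allotype fits of
#'   the SVD initializer.
#' @return list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(l1Bound = 50, multistart = 20L, seed = 1L,
                      initializer = c("random", "zeros", "svd-combined"),
                      startRange = 0.5, epsilon = NULL, gtol = 1e-6,
                      maxit = 2000L, kT = 0.592, rtaMultistart = 3L) {
  initializer <- match.arg(initializer)
  stopifnot(multistart >= 1L, all(l1Bound >= 0), maxit >= 1L, gtol > 0,
            kT > 0, is.null(epsilon) || epsilon > 0)
  structure(list(l1Bound = l1Bound, multistart = as.integer(multistart),
                 seed = as.integer(seed), initializer = initializer,
                 startRange = startRange, epsilon = epsilon, gtol = gtol,
                 maxit = as.integer(maxit), kT = kT,
                 rtaMultistart = as.integer(rtaMultistart)),
            class = "fitConfig")
}

# ---- projection and solver -------------------------------------------------

# Euclidean projection of v onto {u >= 0, sum(u) <= t} (Duchi-style simplex
# threshold). With the beta = beta+ - beta- split this realizes the L1 ball
# constraint sum|beta| <= t.
.projectCappedSimplex <- function(v, t) {
  u <- pmax(v, 0)
  s <- sum(u)
  if (s <= t) return(u)
  if (t <= 0) return(numeric(length(v)))
  sv <- sort(u, decreasing = TRUE)
  css <- cumsum(sv)
  rho <- max(which(sv - (css - t) / seq_along(sv) > 0))
  pmax(u - (css[rho] - t) / rho, 0)
}

# Spectral projected gradient (Birgin-Martinez) with nonmonotone Armijo
# line search. fn/gr operate on the full split vector u.
.spg <- function(u0, fn, gr, t, maxit = 2000L, gtol = 1e-6, memory = 10L) {
  u <- .projectCappedSimplex(u0, t)
  f <- fn(u)
  g <- gr(u)
  fhist <- rep(f, memory)
  alpha <- 1 / max(1e-8, max(abs(g)))
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    pg <- .projectCappedSimplex(u - g, t) - u
    if (max(abs(pg)) < gtol) { converged <- TRUE; break }
    d <- .projectCappedSimplex(u - alpha * g, t) - u
    gd <- sum(g * d)
    if (gd > -1e-18) { converged <- TRUE; break }  # no descent available
    lam <- 1
    fmax <- max(fhist)
    repeat {
      unew <- u + lam * d
      fnew <- fn(unew)
      if (fnew <= fmax + 1e-4 * lam * gd || lam < 1e-12) break
      lam <- lam / 2
    }
    gnew <- gr(unew)
    s <- unew - u
    y <- gnew - g
    sy <- sum(s * y)
    alpha <- if (sy > 1e-14) min(1e10, max(1e-10, sum(s * s) / sy)) else 1e4
    u <- unew; f <- fnew; g <- gnew
    fhist <- c(fhist[-1L], f)
  }
  list(u = u, value = f, iterations = it, converged = converged)
}

# ---- objective assembly ----------------------------------------------------

# Precompute everything the MSE objective and its gradient need.
.assembleFit <- function(dataset, catalog, profiles) {
  rec <- dataset@records
  peptIdx <- lapply(rec$peptide, .encodeIdx)
  prof <- profiles[rec$allele]
  bad <- vapply(prof, is.null, logical(1))
  if (any(bad))
    stop("no profile for allele(s): ",
         paste(unique(rec$allele[bad]), collapse = ", "))
  for (p in prof[!duplicated(rec$allele)]) .checkCompatible(p, catalog)
  des <- .registerDesign(peptIdx, prof, catalog)
  list(Phi = des$Phi, nreg = des$nreg, dGexp = rec$dG,
       n = nrow(rec), P = ncol(des$Phi))
}

# MSE of the Boltzmann-averaged predictions and its gradient wrt beta.
.mseObjective <- function(asm, kT) {
  Phi <- asm$Phi; nreg <- asm$nreg; dGexp <- asm$dGexp; n <- asm$n
  fn <- function(beta) {
    e <- as.numeric(Phi %*% beta)
    b <- .boltzmannByRecord(e, nreg, kT)
    mean((b$dG - dGexp)^2)
  }
  gr <- function(beta) {
    e <- as.numeric(Phi %*% beta)
    b <- .boltzmannByRecord(e, nreg, kT)
    resid <- b$dG - dGexp
    # d dG_k / d e_r = w_r (1 + (e_r - dG_k)/kT) for register row r of k
    coef <- (2 / n) * resid[b$rec] * b$w *
      (1 + (e - b$dG[b$rec]) / kT)
    as.numeric(Matrix::crossprod(Phi, coef))
  }
  list(fn = fn, gr = gr)
}

.splitObjective <- function(obj, P) {
  list(fn = function(u) obj$fn(u[1:P] - u[(P + 1):(2 * P)]),
       gr = function(u) {
         g <- obj$gr(u[1:P] - u[(P + 1):(2 * P)])
         c(g, -g)
       })
}

# ---- fitting ---------------------------------------------------------------

.fitCore <- function(dataset, catalog, profiles, config, extraStarts = list()) {
  asm <- .assembleFit(dataset, catalog, profiles)
  obj <- .mseObjective(asm, config$kT)
  sobj <- .splitObjective(obj, asm$P)
  # parameters never touched by the training data (e.g. groups carried by
  # no training allotype) are pinned to zero, the convention used when
  # predicting allotypes with unrepresented variant groups
  unused <- which(Matrix::colSums(asm$Phi != 0) == 0)
  set.seed(config$seed)
  nstart <- config$multistart
  tGrid <- config$l1Bound
  starts <- vector("list", nstart)
  tUsed <- numeric(nstart)
  for (s in seq_len(nstart)) {
    tUsed[s] <- if (length(tGrid) > 1L) sample(tGrid, 1L) else tGrid
    b0 <- if (s == 1L || config$initializer == "zeros")
      numeric(asm$P)
    else
      runif(asm$P, -config$startRange, config$startRange)
    b0[unused] <- 0
    starts[[s]] <- b0
  }
  for (b0 in extraStarts) {
    b0[unused] <- 0
    starts[[length(starts) + 1L]] <- b0
    tUsed <- c(tUsed, if (length(tGrid) > 1L) max(tGrid) else tGrid)
  }
  best <- NULL
  log <- data.frame(start = integer(), t = numeric(), mse = numeric(),
                    iterations = integer(), converged = logical())
  for (s in seq_along(starts)) {
    u0 <- c(pmax(starts[[s]], 0), pmax(-starts[[s]], 0))
    res <- .spg(u0, sobj$fn, sobj$gr, tUsed[s],
                maxit = config$maxit, gtol = config$gtol)
    log[s, ] <- list(s, tUsed[s], res$value, res$iterations, res$converged)
    if (is.null(best) || res$value < best$value)
      best <- c(res, list(t = tUsed[s]))
  }
  if (!any(log$converged) && all(log$iterations >= config$maxit))
    warning("no start converged within maxit; returning best iterate")
  beta <- best$u[1:asm$P] - best$u[(asm$P + 1):(2 * asm$P)]
  beta[abs(beta) < 1e-12] <- 0
  beta[unused] <- 0
  list(beta = beta, mse = obj$fn(beta), t = best$t, log = log,
       sumAbs = sum(abs(beta)))
}

#' Fit the pan-allotype model by L1-constrained MSE minimization
#'
#' Minimizes the mean square error between Boltzmann-averaged predicted and
#' experimental affinities over the parameter tensor beta, subject to
#' sum |beta| <= t. The problem is smooth but nonconvex (the register
#' average couples parameters nonlinearly), so the solver runs seeded
#' multistart local solves: each start splits beta into nonnegative parts
#' beta+ and beta- with the single linear constraint sum(beta+ + beta-) <= t
#' and descends by spectral projected gradient with analytic gradients. The
#' best local optimum is returned with the full start log.
#'
#' @param dataset a [TrainingDataset-class].
#' @param catalog a [GroupCatalog-class].
#' @param profiles named list of [AllotypeProfile-class], covering every
#'   allele in the dataset.
#' @param config a [fitConfig()] list.
#' @return a [FitResult-class].
#' @seealso [fitRTA()], [svdInitialize()], [leaveOneAlleleOut()]
#' @export
fitPanRTA <- function(dataset, catalog, profiles, config = fitConfig()) {
  if (!inherits(config, "fitConfig")) stop("config must come from fitConfig()")
  if (!nrow(dataset@records)) stop("dataset is empty")
  extra <- list()
  if (config$initializer == "svd-combined") {
    alleles <- unique(dataset@records$allele)
    rtaCfg <- fitConfig(l1Bound = max(config$l1Bound),
                        multistart = config$rtaMultistart,
                        seed = config$seed + 1L, initializer = "random",
                        startRange = config$startRange, gtol = config$gtol,
                        maxit = config$maxit, kT = config$kT)
    rtaMats <- lapply(alleles, function(a) {
      sub <- new("TrainingDataset",
                 records = dataset@records[dataset@records$allele == a, ,
                                           drop = FALSE],
                 unit = dataset@unit)
      rtaMatrix(fitRTA(sub, l1Bound = max(config$l1Bound), config = rtaCfg))
    })
    names(rtaMats) <- alleles
    ini <- svdInitialize(rtaMats, profiles[alleles], catalog,
                         epsilon = config$epsilon)
    extra <- list(unlist(lapply(ini$beta, as.numeric), use.names = FALSE))
  }
  fit <- .fitCore(dataset, catalog, profiles, config, extraStarts = extra)
  model <- new("ModelParams", catalog = catalog,
               beta = .unflattenBeta(catalog, fit$beta), kT = config$kT,
               l1Bound = fit$t,
               trainingAllotypes = unique(dataset@records$allele),
               metadata = list(seed = config$seed,
                               initializer = config$initializer))
  new("FitResult", model = model, mse = fit$mse,
      constraintActive = fit$t - fit$sumAbs <= 1e-6 * max(1, fit$t),
      nNonzero = sum(fit$beta != 0), startLog = fit$log,
      config = unclass(config))
}

# A catalog with no polymorphic groups: the single-allotype model index
# space (only l = 0 at every position).
.rtaCatalog <- function(name = "RTA") {
  new("GroupCatalog", panel = name,
      contacts = new("ContactMap"),
      metadata = list(numbering = "none (single-allotype model)"))
}

.rtaProfile <- function(name = "RTA") {
  new("AllotypeProfile", name = name,
      membership = rep(list(1), N_CORE))
}

#' Fit a single-allotype model
#'
#' The single-type special case: energies depend only on the 9 x 20 matrix
#' beta[i, j] (no group structure), fitted by the same L1-constrained
#' multistart minimization as [fitPanRTA()]. Used directly for
#' nearest-allotype baselines and as input to [svdInitialize()].
#'
#' @param dataset a [TrainingDataset-class] whose records all share one
#'   allotype.
#' @param l1Bound the L1 bound t (kcal/mol).
#' @param config a [fitConfig()] list (its \code{l1Bound} is overridden).
#' @return a [FitResult-class] over the degenerate single-allotype catalog;
#'   extract the matrix with [rtaMatrix()].
#' @export
fitRTA <- function(dataset, l1Bound = 50, config = fitConfig()) {
  rec <- dataset@records
  if (!nrow(rec)) stop("dataset is empty")
  if (length(unique(rec$allele)) != 1L)
    stop("fitRTA requires records for a single allotype; got: ",
         paste(unique(rec$allele), collapse = ", "))
  name <- rec$allele[1L]
  cat0 <- .rtaCatalog(name)
  prof <- setNames(list(.rtaProfile(name)), name)
  config$l1Bound <- l1Bound
  config$initializer <- if (config$initializer == "svd-combined")
    "random" else config$initializer
  fit <- .fitCore(dataset, cat0, prof, config)
  model <- new("ModelParams", catalog = cat0,
               beta = .unflattenBeta(cat0, fit$beta), kT = config$kT,
               l1Bound = fit$t, trainingAllotypes = name,
               metadata = list(seed = config$seed, type = "single-allotype"))
  new("FitResult", model = model, mse = fit$mse,
      constraintActive = fit$t - fit$sumAbs <= 1e-6 * max(1, fit$t),
      nNonzero = sum(fit$beta != 0), startLog = fit$log,
      config = unclass(config))
}

#' Extract the 9 x 20 parameter matrix of a single-allotype fit
#'
#' @param fit a [FitResult-class] from [fitRTA()] (or any model whose
#'   catalog has no polymorphic groups).
#' @return 9 x 20 matrix (rows P1..P9, columns amino acids).
#' @export
rtaMatrix <- function(fit) {
  model <- if (methods::is(fit, "FitResult")) fit@model else fit
  if (any(nGroups(model) != 0L))
    stop("model has polymorphic groups; not a single-allotype fit")
  t(vapply(model@beta, function(b) b[, 1L], numeric(20L)))
}

#' SVD-based initializer combining single-allotype models
#'
#' For each core position i and residue type j, finds the group parameters
#' beta0[i, j, ] whose membership-weighted sum best reproduces the
#' single-allotype coefficients (beta_a)[i, j] across the panel, in the
#' least-squares sense: beta0 = Z+ c, where Z is the allotype x group
#' membership matrix at position i and Z+ its pseudoinverse with singular
#' values below \code{epsilon} zeroed. On rank-deficient Z this yields the
#' minimum-norm least-squares solution.
#'
#' @param rtaMats named list (one per allotype) of 9 x 20 matrices from
#'   [rtaMatrix()].
#' @param profiles named list of [AllotypeProfile-class] for the same
#'   allotypes, indexed against \code{catalog}.
#' @param catalog a [GroupCatalog-class].
#' @param epsilon singular-value cutoff; \code{NULL} means 1e-8 times the
#'   largest singular value of each Z.
#' @return list with \code{beta} (list of 20 x (Ng(i)+1) matrices) and
#'   \code{residual} (9 x 20 matrix of least-squares residual norms r).
#' @export
svdInitialize <- function(rtaMats, profiles, catalog, epsilon = NULL) {
  if (is.null(names(rtaMats)) || !all(names(rtaMats) %in% names(profiles)))
    stop("rtaMats and profiles must be named consistently")
  alleles <- names(rtaMats)
  ng <- nGroups(catalog)
  for (a in alleles) .checkCompatible(profiles[[a]], catalog)
  bad <- !vapply(rtaMats, function(m)
    is.matrix(m) && all(dim(m) == c(N_CORE, 20L)), logical(1))
  if (any(bad)) stop("each rtaMats entry must be a 9 x 20 matrix")
  beta <- vector("list", N_CORE)
  residual <- matrix(0, N_CORE, 20L, dimnames = list(NULL, AA_CODES))
  for (i in seq_len(N_CORE)) {
    Z <- matrix(unlist(lapply(alleles, function(a)
      profiles[[a]]@membership[[i]]), use.names = FALSE),
      ncol = ng[i] + 1L, byrow = TRUE)
    C <- matrix(unlist(lapply(alleles, function(a) rtaMats[[a]][i, ]),
                       use.names = FALSE), ncol = 20L, byrow = TRUE)
    sv <- svd(Z)
    eps <- if (is.null(epsilon)) 1e-8 * max(sv$d) else epsilon
    dplus <- ifelse(sv$d >= eps, 1 / sv$d, 0)
    B <- sv$v %*% (dplus * (t(sv$u) %*% C))   # (Ng+1) x 20
    beta[[i]] <- t(B)
    dimnames(beta[[i]]) <- list(AA_CODES, paste0("l", 0:ng[i]))
    residual[i, ] <- sqrt(colSums((Z %*% B - C)^2))
  }
  list(beta = beta, residual = residual)
}
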