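# Hand-built tiny catalog: one polymorphic group at P1 (residue 86, type G)
# and one at P4 (residue 74, type A). Two allotypes: ALLO1 carries both
# groups, ALLO2 neither.
tinyCatalog <- function() {
  groups <- rep(list(list()), 9L)
  groups[[1]] <- list(data.frame(resno = 86L, type = "G",
                                 stringsAsFactors = FALSE))
  groups[[4]] <- list(data.frame(resno = 74L, type = "A",
                                 stringsAsFactors = FALSE))
  new("GroupCatalog", groups = groups,
      invariant = rep(list(data.frame(resno = integer(),
                                      type = character(),
                                      stringsAsFactors = FALSE)), 9L),
      panel = c("ALLO1", "ALLO2"),
      contacts = contactMap(data.frame(core_pos = c(1L, 4L),
                                       resno = c(86L, 74L))),
      metadata = list(numbering = "test"))
}

tinyProfile <- function(name = "ALLO1", p1 = 1, p4 = 1) {
  membership <- rep(list(1), 9L)
  membership[[1]] <- c(1, p1)
  membership[[4]] <- c(1, p4)
  new("AllotypeProfile", name = name, membership = membership)
}

# Random dense model over a catalog, deterministic given seed.
randomModel <- function(catalog, seed = 1, kT = 0.592, scale = 1) {
  set.seed(seed)
  ng <- nGroups(catalog)
  beta <- lapply(seq_len(9L), function(i) {
    matrix(runif(20 * (ng[i] + 1), -scale, scale), nrow = 20,
           dimnames = list(panRTA:::AA_CODES, paste0("l", 0:ng[i])))
  })
  new("ModelParams", catalog = catalog, beta = beta, kT = kT,
      l1Bound = Inf, trainingAllotypes = catalog@panel)
}

zeroModel <- function(catalog, kT = 0.592) {
  m <- randomModel(catalog, 1, kT)
  m@beta <- lapply(m@beta, function(b) { b[] <- 0; b })
  m
}

randomPeptide <- function(L) {
  paste(sample(panRTA:::AA_CODES, L, replace = TRUE), collapse = "")
}

# Independent brute-force oracle for register energies: explicit triple
# loop over positions, residue types and groups.
oracleRegisterEnergy <- function(peptide, profile, model, M) {
  chars <- strsplit(peptide, "")[[1]]
  total <- 0
  for (i in 1:9) {
    j <- match(chars[i + M], panRTA:::AA_CODES)
    z <- membership(profile)[[i]]
    for (l in seq_along(z))
      total <- total + model@beta[[i]][j, l] * z[l]
  }
  total
}

# Direct evaluation of the register-average formula without max-shift.
oracleAverage <- function(e, kT) {
  sum(e * exp(e / kT)) / sum(exp(e / kT))
}

benchFile <- function(name) {
  system.file("extdata", "benchmarks", name, package = "panRTA")
}

# Shared expensive leave-one-allele-out fixture: 4 allotypes with full
# transfer coverage, 1000 records per allotype, 0.5 kcal/mol noise.
.fixtureCache <- new.env(parent = emptyenv())

loaoFixture <- function() {
  if (!is.null(.fixtureCache$loao)) return(.fixtureCache$loao)
  spec <- syntheticSpec(seed = 11, nAllotypes = 4, nPerAllotype = 1000,
                        noise = 0.5, minGroupCount = 2)
  gt <- genGroundTruth(spec)
  ds <- genDataset(gt, spec)
  cfg <- fitConfig(l1Bound = 150, multistart = 2, seed = 2,
                   initializer = "svd-combined", rtaMultistart = 2,
                   maxit = 4000)
  cv <- suppressWarnings(
    leaveOneAlleleOut(ds, gt$catalog, gt$profiles, cfg,
                      alleles = "SYN*01"))
  .fixtureCache$loao <- list(spec = spec, gt = gt, ds = ds, cv = cv)
  .fixtureCache$loao
}

# Brute-force oracle: partition variants at one position by equality of
# their occurrence sets over the panel.
oraclePartition <- function(panel, resnos) {
  chars <- lapply(panel, function(s) strsplit(s, "")[[1]])
  variants <- list()
  for (rn in resnos)
    for (tp in unique(vapply(chars, `[`, character(1), rn)))
      variants[[length(variants) + 1L]] <- list(
        resno = rn, type = tp,
        occ = sort(names(panel)[vapply(chars, `[`, character(1),
                                       rn) == tp]))
  keys <- vapply(variants, function(v)
    paste(v$occ, collapse = "|"), character(1))
  split(variants, keys)
}

# O(n^2) pair-counting oracle: concordant pairs + half ties.
oracleAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Full 2^n enumeration oracle for the exact signed-rank test.
oracleWilcoxon <- function(a, b) {
  d <- a - b; d <- d[d != 0]; n <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[bits])
  }, numeric(1))
  mean(ws >= wobs)
}
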