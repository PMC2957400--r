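#' Specification of a synthetic study
#'
#' Defines the generative conditions for ground-truth models and noisy
#' affinity datasets with exactly the statistical structure the fitting
#' assumes. Defaults emulate a class II binding panel: five allotypes (the
#' size of an HLA-DP training panel), one variant group at the P1- and
#' P8-like positions and two elsewhere (P1 variation in HLA-DR reduces to a
#' single dimorphism), 15-25-mer peptides, sparse contributions up to
#' 2 kcal/mol giving register energies spread over a few kcal/mol as in
#' competition-assay compilations, and 0.5 kcal/mol Gaussian measurement
#' noise (about 0.4 log10 IC50 units, typical assay reproducibility).
#'
#' @param seed integer RNG seed; all generators are pure functions of the
#'   spec including this seed.
#' @param nAllotypes number of panel allotypes.
#' @param groupsPerPosition integer vector of length 9: polymorphic groups
#'   at each core position (each must be <= nAllotypes so every group can
#'   occur).
#' @param sparsity fraction of nonzero ground-truth beta entries, in (0, 1].
#' @param scale half-width of the uniform distribution of nonzero beta
#'   values (kcal/mol).
#' @param lengthRange integer range of peptide lengths, min >= 9.
#' @param nPerAllotype affinity records generated per allotype.
#' @param noise standard deviation of additive Gaussian affinity noise
#'   (kcal/mol).
#' @param kT thermal energy of the register average (kcal/mol).
#' @param minGroupCount minimum number of allotypes carrying each group
#'   (default 1). Use 2 to guarantee that holding out any single allotype
#'   leaves every group represented in training (full transfer coverage);
#'   requires \code{nAllotypes >= max(groupsPerPosition) * minGroupCount}.
#' @return list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(seed = 1L, nAllotypes = 5L,
                          groupsPerPosition = c(1L, 2L, 2L, 2L, 2L, 2L,
                                                2L, 1L, 2L),
                          sparsity = 0.25, scale = 2.0,
                          lengthRange = c(15L, 25L), nPerAllotype = 500L,
                          noise = 0.5, kT = 0.592, minGroupCount = 1L) {
  stopifnot(length(groupsPerPosition) == 9L, all(groupsPerPosition >= 0L),
            nAllotypes >= 1L, sparsity > 0, sparsity <= 1, scale > 0,
            length(lengthRange) == 2L, lengthRange[1L] >= 9L,
            lengthRange[2L] >= lengthRange[1L], nPerAllotype >= 1L,
            noise >= 0, kT > 0, minGroupCount >= 1L)
  structure(list(seed = as.integer(seed), nAllotypes = as.integer(nAllotypes),
                 groupsPerPosition = as.integer(groupsPerPosition),
                 sparsity = sparsity, scale = scale,
                 lengthRange = as.integer(lengthRange),
                 nPerAllotype = as.integer(nPerAllotype), noise = noise,
                 kT = kT, minGroupCount = as.integer(minGroupCount)),
            class = "syntheticSpec")
}

#' Generate a ground-truth catalog, panel and parameter tensor
#'
#' Builds a synthetic group catalog with the requested number of groups per
#' position (each group a single polymorphic residue variant; the groups at
#' one position form a mutually exclusive family, as produced by profiling
#' real sequences), assigns each allotype one group per position at random
#' such that every group occurs in at least one allotype, and draws a
#' sparse ground-truth parameter tensor. Deterministic given the spec.
#'
#' @param spec a [syntheticSpec()] list.
#' @return list with \code{catalog} ([GroupCatalog-class]),
#'   \code{profiles} (named list of [AllotypeProfile-class]) and
#'   \code{model} ([ModelParams-class] holding the ground-truth beta).
#' @export
genGroundTruth <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  if (any(spec$groupsPerPosition * spec$minGroupCount > spec$nAllotypes))
    stop("cannot place ", max(spec$groupsPerPosition),
         " mutually exclusive groups with >= ", spec$minGroupCount,
         " carriers each among ", spec$nAllotypes,
         " allotypes: membership constraints unsatisfiable")
  set.seed(spec$seed)
  g <- spec$groupsPerPosition
  nA <- spec$nAllotypes
  anames <- sprintf("SYN*%02d", seq_len(nA))
  groups <- rep(list(list()), N_CORE)
  pairs <- list()
  assign <- vector("list", N_CORE)  # allotype -> group index per position
  for (i in seq_len(N_CORE)) {
    if (g[i] == 0L) { assign[[i]] <- rep(0L, nA); next }
    rn <- 10L + 5L * i  # arbitrary but fixed panel numbering
    groups[[i]] <- lapply(seq_len(g[i]), function(l)
      data.frame(resno = rn, type = AA_CODES[l], stringsAsFactors = FALSE))
    pairs[[length(pairs) + 1L]] <- data.frame(core_pos = i, resno = rn)
    repeat {  # each group must reach its minimum carrier count
      cat_i <- sample.int(g[i], nA, replace = TRUE)
      if (all(tabulate(cat_i, g[i]) >= spec$minGroupCount)) break
    }
    assign[[i]] <- cat_i
  }
  cm <- contactMap(if (length(pairs)) do.call(rbind, pairs) else
    data.frame(core_pos = integer(), resno = integer()),
    provenance = "synthetic")
  catalog <- new("GroupCatalog", groups = groups,
                 invariant = rep(list(data.frame(resno = integer(),
                                                 type = character(),
                                                 stringsAsFactors = FALSE)),
                                 N_CORE),
                 panel = anames, contacts = cm,
                 metadata = list(numbering = "synthetic", seed = spec$seed))
  profiles <- lapply(seq_len(nA), function(a) {
    membership <- lapply(seq_len(N_CORE), function(i) {
      z <- c(1, numeric(g[i]))
      if (g[i] > 0L) z[assign[[i]][a] + 1L] <- 1
      z
    })
    new("AllotypeProfile", name = anames[a], membership = membership)
  })
  names(profiles) <- anames
  beta <- lapply(seq_len(N_CORE), function(i) {
    m <- matrix(0, 20L, g[i] + 1L,
                dimnames = list(AA_CODES, paste0("l", 0:g[i])))
    nz <- matrix(runif(length(m)) < spec$sparsity, nrow(m))
    m[nz] <- runif(sum(nz), -spec$scale, spec$scale)
    m
  })
  model <- new("ModelParams", catalog = catalog, beta = beta, kT = spec$kT,
               l1Bound = Inf, trainingAllotypes = anames,
               metadata = list(groundTruth = TRUE, seed = spec$seed))
  list(catalog = catalog, profiles = profiles, model = model)
}

#' Generate a noisy affinity dataset from a ground truth
#'
#' Peptides are uniform-random over the 20 residue types with lengths
#' uniform in the spec's range; allotypes are assigned round-robin;
#' experimental affinities are the ground-truth Boltzmann-averaged energies
#' plus Gaussian noise. Deterministic given (ground truth, spec).
#'
#' @param groundTruth output of [genGroundTruth()].
#' @param spec the [syntheticSpec()] used (noise, lengths and counts are
#'   read from it).
#' @return a [TrainingDataset-class].
#' @export
genDataset <- function(groundTruth, spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  profiles <- groundTruth$profiles
  model <- groundTruth$model
  nA <- length(profiles)
  n <- nA * spec$nPerAllotype
  set.seed(spec$seed + 1L)
  span <- spec$lengthRange[2L] - spec$lengthRange[1L] + 1L
  lens <- spec$lengthRange[1L] + sample.int(span, n, replace = TRUE) - 1L
  peptides <- vapply(lens, function(L)
    paste(sample(AA_CODES, L, replace = TRUE), collapse = ""), character(1))
  alleles <- rep_len(names(profiles), n)
  dG <- .batchPredict(peptides, alleles, profiles, model) +
    rnorm(n, 0, spec$noise)
  new("TrainingDataset",
      records = data.frame(peptide_id = sprintf("pep%05d", seq_len(n)),
                           peptide = peptides, allele = alleles, dG = dG,
                           stringsAsFactors = FALSE),
      unit = "kcal/mol")
}

#' Write a miniature peptide-MHC structure fixture
#'
#' Produces a two-chain PDB exercising the heavy-atom contact rule by
#' construction: a 9-residue peptide chain (C) and an MHC chain (B) with
#' one residue at 3.5 A of core position 2 (a contact), one at exactly
#' 4.0 A of core position 3 (not a contact: strict inequality), one whose
#' hydrogen is at 1.0 A of core position 4 but whose heavy atoms are at
#' 4.5 A (not a contact), and one at 2.0 A of core position 1 (a contact).
#'
#' @param file output PDB path.
#' @param scale multiplier applied to all coordinates; \code{scale = 2}
#'   doubles every distance so no contact remains.
#' @return invisibly, a list with \code{file}, \code{coreResno} (the core
#'   annotation for [extractContacts()]) and \code{expected} (the planted
#'   contact pairs at \code{scale = 1}).
#' @export
genStructureFixture <- function(file, scale = 1) {
  # peptide chain C: residues 1..9, CA atoms spaced 20 A apart on x
  pep <- data.frame(resno = 1:9, x = (0:8) * 20, y = 0, z = 0)
  # MHC chain B residues placed relative to specific core residues
  mhc <- data.frame(
    resno = c(101L, 102L, 103L, 103L, 104L),
    elety = c("CB", "CB", "CB", "H", "CB"),
    elesy = c("C", "C", "C", "H", "C"),
    x = c(pep$x[2], pep$x[3], pep$x[4], pep$x[4], pep$x[1]),
    y = c(3.5, 4.0, 4.5, 1.0, 2.0),
    z = 0)
  xyz <- rbind(cbind(pep$x, pep$y, pep$z),
               cbind(mhc$x, mhc$y, mhc$z)) * scale
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(xyz)),
    resno = c(pep$resno, mhc$resno),
    resid = rep("ALA", nrow(pep) + nrow(mhc)),
    chain = c(rep("C", nrow(pep)), rep("B", nrow(mhc))),
    eleno = seq_len(nrow(pep) + nrow(mhc)),
    elety = c(rep("CA", nrow(pep)), mhc$elety),
    elesy = c(rep("C", nrow(pep)), mhc$elesy))
  invisible(list(file = file, coreResno = 1:9,
                 expected = data.frame(core_pos = c(1L, 2L),
                                       resno = c(104L, 101L))))
}
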