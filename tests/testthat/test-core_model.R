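test_that("one-hot encoding places each residue in its documented column", {
  m <- encodePeptide("AAAAAAAAA")
  expect_equal(dim(m), c(9L, 20L))
  expect_true(all(m[, "A"] == 1L))
  expect_equal(sum(m), 9L)

  m2 <- encodePeptide("ACDEFGHIK")
  expect_equal(rowSums(m2), rep(1, 9))
  expect_equal(length(unique(max.col(m2))), 9L)
  expect_equal(colnames(m2)[max.col(m2)],
               strsplit("ACDEFGHIK", "")[[1]])
})

test_that("encoding rejects bad input naming the offending position", {
  expect_error(encodePeptide("ACDEFGHBX"), "position 8")
  expect_error(encodePeptide("ACDEFGHBX"), "'B'")
  expect_error(encodePeptide("ACDEFGHI"), "shorter")
})

test_that("register energy matches a hand sum and the brute-force oracle", {
  cat1 <- tinyCatalog()
  model <- zeroModel(cat1)

  # zero model: every register zero
  prof <- tinyProfile()
  for (M in 0:6)
    expect_identical(registerEnergy(paste(rep("F", 15), collapse = ""),
                                    prof, model, M), 0)

  # two-term hand sum: beta[P1, F, l0] = 1.0, beta[P1, F, l1] = 0.5
  model@beta[[1]]["F", "l0"] <- 1.0
  model@beta[[1]]["F", "l1"] <- 0.5
  expect_equal(registerEnergy("FAAAAAAAA", tinyProfile(p1 = 1), model, 0),
               1.5)
  expect_equal(registerEnergy("FAAAAAAAA", tinyProfile(p1 = 0), model, 0),
               1.0)

  # seeded random model vs independent triple-loop summation
  rmodel <- randomModel(cat1, seed = 42)
  set.seed(7)
  for (rep in 1:5) {
    pep <- randomPeptide(sample(9:20, 1))
    prof <- tinyProfile(p1 = sample(0:1, 1), p4 = sample(0:1, 1))
    M <- sample(0:(nchar(pep) - 9), 1)
    expect_equal(registerEnergy(pep, prof, rmodel, M),
                 oracleRegisterEnergy(pep, prof, rmodel, M),
                 tolerance = 1e-12)
  }
})

test_that("register energy rejects out-of-range registers and catalog mismatch", {
  model <- randomModel(tinyCatalog())
  expect_error(registerEnergy("FAAAAAAAA", tinyProfile(), model, 1),
               "out of range")
  expect_error(registerEnergy("FAAAAAAAA", tinyProfile(), model, -1),
               "out of range")
  wrong <- new("AllotypeProfile", name = "X",
               membership = rep(list(1), 9L))  # no group slots
  expect_error(registerEnergy("FAAAAAAAA", wrong, model, 0),
               "different catalog")
})

test_that("thermodynamic average has the closed-form values and limits", {
  expect_equal(thermodynamicAverage(2.5, kT = 1)$dG, 2.5)
  expect_equal(thermodynamicAverage(c(3, 3, 3), kT = 0.1)$dG, 3)
  ta <- thermodynamicAverage(c(0, log(3)), kT = 1)
  expect_equal(ta$dG, 3 * log(3) / 4, tolerance = 1e-12)
  expect_equal(unname(ta$weights), c(1 / 4, 3 / 4), tolerance = 1e-12)

  set.seed(1)
  for (rep in 1:10) {
    e <- rnorm(sample(2:12, 1), sd = 2)
    # kT -> 0: best register; kT -> Inf: arithmetic mean
    expect_equal(thermodynamicAverage(e, 1e-6)$dG, max(e),
                 tolerance = 1e-9)
    # deviation from the mean is O(var(e)/kT) at large kT
    expect_lt(abs(thermodynamicAverage(e, 1e6)$dG - mean(e)), 1e-4)
    ta <- thermodynamicAverage(e, 0.592)
    expect_gte(ta$dG, min(e))
    expect_lte(ta$dG, max(e))
    expect_equal(sum(ta$weights), 1, tolerance = 1e-12)
    # agreement with the naive unshifted formula where it is stable
    expect_equal(ta$dG, oracleAverage(e, 0.592), tolerance = 1e-12)
    # shifting all register energies by c shifts the average by exactly c
    for (c in c(-1000, 1000))
      expect_equal(thermodynamicAverage(e + c, 0.592)$dG, ta$dG + c,
                   tolerance = 1e-9)
  }
  expect_error(thermodynamicAverage(numeric(0), 1), "non-empty")
  expect_error(thermodynamicAverage(c(1, 2), 0), "positive")
  expect_error(thermodynamicAverage(c(1, 2), -1), "positive")
})

test_that("prediction equals explicit register enumeration", {
  cat1 <- tinyCatalog()
  model <- randomModel(cat1, seed = 3)
  prof <- tinyProfile()

  # 9-mer: one register, prediction is that register's energy
  rs <- predictAffinity("FAAAAAAAA", prof, model)
  expect_length(registerEnergies(rs), 1L)
  expect_equal(affinity(rs), registerEnergy("FAAAAAAAA", prof, model, 0))
  expect_equal(rankedCores(rs)$core, "FAAAAAAAA")

  # zero model: dG = 0, uniform weights 1/(L - 8)
  set.seed(4)
  pep15 <- randomPeptide(15)
  rs0 <- predictAffinity(pep15, prof, zeroModel(cat1))
  expect_equal(affinity(rs0), 0)
  expect_equal(unname(registerWeights(rs0)), rep(1 / 7, 7))

  # 15-mer: enumeration of the 7 registers + averaging formula, to 1e-12
  rs15 <- predictAffinity(pep15, prof, model)
  e <- vapply(0:6, function(M)
    oracleRegisterEnergy(pep15, prof, model, M), numeric(1))
  expect_equal(unname(registerEnergies(rs15)), e, tolerance = 1e-12)
  expect_equal(affinity(rs15), oracleAverage(e, thermalEnergy(model)),
               tolerance = 1e-12)
  expect_gte(affinity(rs15), min(e))
  expect_lte(affinity(rs15), max(e))
})

test_that("core ranking sorts registers and breaks ties toward the N terminus", {
  cat1 <- tinyCatalog()
  model <- randomModel(cat1, seed = 9)
  prof <- tinyProfile()
  set.seed(5)
  pep <- randomPeptide(18)
  cores <- findCores(pep, prof, model, top_n = 10)
  e <- vapply(0:9, function(M)
    oracleRegisterEnergy(pep, prof, model, M), numeric(1))
  expect_equal(cores$dG_M, sort(e, decreasing = TRUE))
  expect_equal(cores$M, (0:9)[order(-e)])
  expect_equal(cores$gap, cores$dG_M[1] - cores$dG_M)

  # degenerate energies: ties resolve to smaller M
  tied <- findCores(pep, prof, zeroModel(cat1), top_n = 10)
  expect_equal(tied$M, 0:9)

  one <- findCores("ACDEFGHIK", prof, model, top_n = 5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$gap, 0)
})

test_that("IC50 conversions are exact inverses with the documented constants", {
  expect_equal(affinityToIC50(0), 1e9)
  expect_equal(ic50ToAffinity(1000), 0.592 * log(1e6), tolerance = 1e-12)
  set.seed(6)
  x <- 10^runif(20, -1, 7)
  expect_equal(affinityToIC50(ic50ToAffinity(x)), x, tolerance = 1e-9)
  y <- rnorm(20, 7, 2)
  expect_equal(ic50ToAffinity(affinityToIC50(y)), y, tolerance = 1e-9)
  expect_error(ic50ToAffinity(0), "positive")
  expect_error(ic50ToAffinity(-5), "positive")
  # stronger binder (smaller IC50) has larger affinity
  expect_gt(ic50ToAffinity(10), ic50ToAffinity(10000))
})

test_that("group relabeling and missing groups behave as exact symmetries", {
  # permuting group labels (with memberships permuted consistently)
  # leaves every register energy unchanged
  spec <- syntheticSpec(seed = 21, nAllotypes = 4,
                        groupsPerPosition = rep(3L, 9), nPerAllotype = 5)
  gt <- genGroundTruth(spec)
  perm <- c(3L, 1L, 2L)
  pmodel <- gt$model
  pprofiles <- gt$profiles
  for (i in 1:9) {
    pmodel@beta[[i]] <- pmodel@beta[[i]][, c(1L, perm + 1L)]
    for (a in seq_along(pprofiles))
      pprofiles[[a]]@membership[[i]] <-
        pprofiles[[a]]@membership[[i]][c(1L, perm + 1L)]
  }
  set.seed(8)
  pep <- randomPeptide(16)
  for (a in names(gt$profiles))
    expect_equal(
      affinity(predictAffinity(pep, gt$profiles[[a]], gt$model)),
      affinity(predictAffinity(pep, pprofiles[[a]], pmodel)),
      tolerance = 1e-12)

  # a removed group equals a present group with a zeroed beta slice
  lc <- which(gt$profiles[[1]]@membership[[4]][-1] == 1)[1] + 1L
  m0 <- gt$model
  m0@beta[[4]][, lc] <- 0
  pOff <- gt$profiles[[1]]
  pOff@membership[[4]][lc] <- 0
  expect_equal(affinity(predictAffinity(pep, pOff, gt$model)),
               affinity(predictAffinity(pep, gt$profiles[[1]], m0)),
               tolerance = 1e-12)
})
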