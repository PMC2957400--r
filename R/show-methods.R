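setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@pairs), "contact pair(s) from",
      length(object@provenance), "source(s)\n")
  if (nrow(object@pairs)) {
    byPos <- table(factor(object@pairs$core_pos, levels = 1:9))
    cat("  contacts per core position:",
        paste(byPos, collapse = " "), "\n")
  }
})

setMethod("show", "GroupCatalog", function(object) {
  ng <- nGroups(object)
  cat("GroupCatalog over", length(object@panel), "panel allotype(s)\n")
  cat("  polymorphic groups per position:",
      paste(ng, collapse = " "), "(plus invariant l = 0)\n")
  cat("  invariant variants per position:",
      paste(vapply(object@invariant, nrow, integer(1)), collapse = " "),
      "\n")
})

setMethod("show", "AllotypeProfile", function(object) {
  cat("AllotypeProfile:", object@name, "\n")
  cat("  groups carried:",
      sum(unlist(lapply(object@membership, function(z) z[-1L]))),
      "| coverage (group-level):",
      sprintf("%.1f%%", 100 * object@coveredFraction), "\n")
  if (nrow(object@missingGroups))
    cat("  variants missing from catalog:",
        paste(sprintf("P%d:%d%s", object@missingGroups$core_pos,
                      object@missingGroups$resno,
                      object@missingGroups$type), collapse = ", "), "\n")
})

setMethod("show", "ModelParams", function(object) {
  nz <- sum(vapply(object@beta, function(b) sum(b != 0), integer(1)))
  tot <- sum(vapply(object@beta, length, integer(1)))
  cat("ModelParams:", nz, "of", tot, "parameters nonzero\n")
  cat(sprintf("  kT = %.3f kcal/mol | L1 bound t = %s | trained on %d allotype(s)\n",
              object@kT,
              if (is.finite(object@l1Bound))
                sprintf("%.3g", object@l1Bound) else "Inf",
              length(object@trainingAllotypes)))
})

setMethod("show", "RegisterScores", function(object) {
  cat(sprintf("RegisterScores: %s vs %s | %d register(s)\n",
              object@peptideId, object@allotype, length(object@energies)))
  cat(sprintf("  dG = %.3f kcal/mol (IC50 ~ %.3g nM at RT = 0.592)\n",
              object@dG, affinityToIC50(object@dG)))
  top <- object@cores[1L, ]
  cat(sprintf("  primary core: %s (M = %d, dG_M = %.3f)\n",
              top$core, top$M, top$dG_M))
})

setMethod("show", "TrainingDataset", function(object) {
  rec <- object@records
  cat("TrainingDataset:", nrow(rec), "record(s),",
      length(unique(rec$allele)), "allotype(s)\n")
  if (nrow(rec))
    cat(sprintf("  dG range %.2f .. %.2f kcal/mol | peptide lengths %d .. %d\n",
                min(rec$dG), max(rec$dG), min(nchar(rec$peptide)),
                max(nchar(rec$peptide))))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: MSE = %.6g | %d nonzero parameter(s) | constraint %s\n",
              object@mse, object@nNonzero,
              if (object@constraintActive) "active" else "inactive"))
  cat("  starts:", nrow(object@startLog), "| best t =",
      sprintf("%.3g", object@model@l1Bound), "\n")
})

setMethod("show", "SpecificityProfile", function(object) {
  cat("SpecificityProfile:", object@allotype, "\n")
  cat("  sigma (kcal/mol):",
      paste(sprintf("P%d=%.2f", 1:9, object@sigma), collapse = " "), "\n")
})
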