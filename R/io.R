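# Tabular outputs are tab-separated, one header row, numerics at 6
# significant digits.
.writeTSV <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readDelim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  else read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a peptide affinity table
#'
#' Accepts TSV or CSV with columns \code{peptide}, \code{allele} and either
#' \code{ic50_nM} or \code{dG_kcal} (an optional \code{peptide_id} column is
#' honored). IC50 values are converted to the affinity scale on load.
#' Unparseable rows (non-numeric or non-positive IC50, non-canonical
#' peptide characters) are skipped and counted in a message, as are
#' peptides failing the length filter.
#'
#' @param path file path.
#' @param units \code{"auto"} (pick by column present), \code{"ic50_nM"} or
#'   \code{"kcal/mol"}.
#' @param minLength peptide length filter; records below it are dropped.
#'   Use 15 to mirror data handling that requires full-length class II
#'   ligands, 9 (default) for the model's minimum.
#' @param RT IC50 conversion constant (kcal/mol).
#' @return a [TrainingDataset-class].
#' @export
readAffinityTable <- function(path, units = c("auto", "ic50_nM",
                                              "kcal/mol"),
                              minLength = 9L, RT = 0.592) {
  units <- match.arg(units)
  df <- .readDelim(path)
  for (col in c("peptide", "allele"))
    if (!col %in% names(df))
      stop(sprintf("required column '%s' missing from %s", col, path))
  if (units == "auto")
    units <- if ("dG_kcal" %in% names(df)) "kcal/mol" else "ic50_nM"
  valcol <- if (units == "kcal/mol") "dG_kcal" else "ic50_nM"
  if (!valcol %in% names(df))
    stop(sprintf("required column '%s' missing from %s", valcol, path))
  raw <- suppressWarnings(as.numeric(df[[valcol]]))
  peptide <- toupper(trimws(df$peptide))
  okParse <- !is.na(raw) & !is.na(peptide) & nzchar(peptide) &
    !grepl(sprintf("[^%s]", paste(AA_CODES, collapse = "")), peptide)
  if (units == "ic50_nM") okParse <- okParse & raw > 0
  nBad <- sum(!okParse)
  if (nBad) message(nBad, " unparseable row(s) skipped")
  okLen <- nchar(peptide) >= minLength
  nShort <- sum(okParse & !okLen)
  if (nShort)
    message(nShort, " peptide(s) shorter than ", minLength, " dropped")
  keep <- okParse & okLen
  dG <- if (units == "ic50_nM") ic50ToAffinity(raw[keep], RT) else raw[keep]
  ids <- if ("peptide_id" %in% names(df)) as.character(df$peptide_id[keep])
    else sprintf("pep%05d", which(keep))
  new("TrainingDataset",
      records = data.frame(peptide_id = ids, peptide = peptide[keep],
                           allele = trimws(as.character(df$allele[keep])),
                           dG = dG, stringsAsFactors = FALSE),
      unit = units)
}

#' Write a dataset back to TSV
#' @param dataset a [TrainingDataset-class].
#' @param path output path.
#' @export
writeAffinityTable <- function(dataset, path) {
  df <- dataset@records
  names(df)[names(df) == "dG"] <- "dG_kcal"
  .writeTSV(df, path)
}

#' Read and write contact maps
#'
#' TSV with columns \code{core_pos} and \code{mhc_residue_number}.
#'
#' @param path file path.
#' @param contacts a [ContactMap-class].
#' @return \code{readContactMap}: a [ContactMap-class].
#' @export
readContactMap <- function(path) {
  df <- .readDelim(path)
  for (col in c("core_pos", "mhc_residue_number"))
    if (!col %in% names(df))
      stop(sprintf("required column '%s' missing from %s", col, path))
  contactMap(data.frame(core_pos = df$core_pos,
                        resno = df$mhc_residue_number),
             provenance = "supplied")
}

#' @rdname readContactMap
#' @export
writeContactMap <- function(contacts, path) {
  .writeTSV(data.frame(core_pos = contacts@pairs$core_pos,
                       mhc_residue_number = contacts@pairs$resno), path)
}

# ---- catalog JSON ----------------------------------------------------------

.catalogToList <- function(catalog) {
  list(panel = catalog@panel,
       numbering = catalog@metadata$numbering,
       contacts = catalog@contacts@pairs,
       positions = lapply(seq_len(N_CORE), function(i) {
         gs <- catalog@groups[[i]]
         list(position = i,
              invariant = catalog@invariant[[i]],
              groups = lapply(seq_along(gs), function(l)
                list(l = l, variants = gs[[l]])))
       }))
}

#' Serialize a group catalog to JSON
#'
#' The JSON lists, per core position, the invariant (l = 0) variants and
#' the polymorphic groups with explicit l indices, plus the panel and the
#' contact map — the same information as a supplementary residue-group
#' table.
#'
#' @param catalog a [GroupCatalog-class].
#' @param path output path.
#' @export
writeGroupCatalog <- function(catalog, path) {
  jsonlite::write_json(.catalogToList(catalog), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' @rdname writeGroupCatalog
#' @return \code{readGroupCatalog}: a [GroupCatalog-class].
#' @export
readGroupCatalog <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  .catalogFromList(x)
}

# x: nested lists as written by writeGroupCatalog (rows as objects)
.catalogFromList <- function(x) {
  emptyVar <- data.frame(resno = integer(), type = character(),
                         stringsAsFactors = FALSE)
  asVar <- function(v) {
    if (is.null(v) || !length(v)) return(emptyVar)
    data.frame(
      resno = vapply(v, function(r) as.integer(r$resno), integer(1)),
      type = vapply(v, function(r) as.character(r$type), character(1)),
      stringsAsFactors = FALSE)
  }
  groups <- rep(list(list()), N_CORE)
  invariant <- rep(list(emptyVar), N_CORE)
  for (p in x$positions) {
    i <- as.integer(p$position)
    invariant[[i]] <- asVar(p$invariant)
    if (length(p$groups))
      groups[[i]] <- lapply(p$groups, function(g) asVar(g$variants))
  }
  cmPairs <- if (length(x$contacts))
    data.frame(
      core_pos = vapply(x$contacts, function(r)
        as.integer(r$core_pos), integer(1)),
      resno = vapply(x$contacts, function(r)
        as.integer(r$resno), integer(1)))
  else data.frame(core_pos = integer(), resno = integer())
  new("GroupCatalog", groups = groups, invariant = invariant,
      panel = as.character(unlist(x$panel)),
      contacts = contactMap(cmPairs, provenance = "imported"),
      metadata = list(numbering = x$numbering))
}

# ---- model JSON ------------------------------------------------------------

# Small content fingerprint (31-ary polynomial hash mod 2^31 - 1) so a
# model records which catalog it was fitted against.
.contentHash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.catalogHash <- function(catalog) {
  .contentHash(jsonlite::toJSON(.catalogToList(catalog), auto_unbox = TRUE,
                          digits = NA))
}

#' Serialize and restore fitted models
#'
#' The JSON stores the nonzero beta entries as (position, residue, group,
#' value) tuples together with kT, the L1 bound, the training allotypes,
#' the embedded catalog and its fingerprint, so a restored model
#' reproduces predictions to full numeric precision.
#'
#' @param model a [ModelParams-class].
#' @param path file path.
#' @export
writeModelParams <- function(model, path) {
  ng <- nGroups(model)
  rows <- list()
  for (i in seq_len(N_CORE)) {
    b <- model@beta[[i]]
    nz <- which(b != 0, arr.ind = TRUE)
    if (nrow(nz))
      rows[[i]] <- data.frame(i = i, j = AA_CODES[nz[, 1L]],
                              l = nz[, 2L] - 1L, value = b[nz],
                              stringsAsFactors = FALSE)
  }
  beta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = character(), l = integer(),
               value = numeric())
  jsonlite::write_json(
    list(kT = model@kT, l1Bound = model@l1Bound,
         trainingAllotypes = model@trainingAllotypes,
         catalogHash = .catalogHash(model@catalog),
         metadata = model@metadata,
         catalog = .catalogToList(model@catalog),
         beta = beta),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname writeModelParams
#' @return \code{readModelParams}: a [ModelParams-class].
#' @export
readModelParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  catalog <- .catalogFromList(x$catalog)
  beta <- .zeroBeta(catalog)
  for (row in x$beta) {
    j <- match(as.character(row$j), AA_CODES)
    if (is.na(j)) stop("unknown residue code in model file")
    beta[[as.integer(row$i)]][j, as.integer(row$l) + 1L] <-
      as.numeric(row$value)
  }
  l1 <- x$l1Bound
  if (is.null(l1) || is.character(l1)) l1 <- Inf
  new("ModelParams", catalog = catalog, beta = beta,
      kT = as.numeric(x$kT), l1Bound = l1,
      trainingAllotypes = as.character(unlist(x$trainingAllotypes)),
      metadata = lapply(x$metadata, unlist))
}

#' Import a published parameter table
#'
#' Reads a delimited list of model parameters (position, residue type,
#' group, value) — the format in which fitted parameter sets are published,
#' typically sorted by decreasing magnitude — against a catalog read with
#' [readGroupCatalog()]. Import is order-insensitive; unmapped entries of
#' the tensor default to zero.
#'
#' @param path TSV/CSV of parameters.
#' @param catalog the [GroupCatalog-class] defining the index space.
#' @param layout named list mapping tensor indices to column names:
#'   \code{position} (core position 1-9), \code{residue} (one-letter code),
#'   \code{group} (integer l, 0 = invariant; or a label like \code{"l2"}),
#'   \code{value} (kcal/mol).
#' @param kT,l1Bound stored in the resulting model (the published tables
#'   do not restate them).
#' @return a [ModelParams-class].
#' @export
importPublishedParameters <- function(path, catalog,
                                      layout = list(position = "i",
                                                    residue = "j",
                                                    group = "l",
                                                    value = "value"),
                                      kT = 0.592, l1Bound = Inf) {
  df <- .readDelim(path)
  for (col in unlist(layout))
    if (!col %in% names(df))
      stop(sprintf("layout column '%s' missing from %s", col, path))
  i <- as.integer(df[[layout$position]])
  j <- match(toupper(trimws(df[[layout$residue]])), AA_CODES)
  lraw <- df[[layout$group]]
  l <- suppressWarnings(as.integer(gsub("^[lL]", "", as.character(lraw))))
  v <- as.numeric(df[[layout$value]])
  if (anyNA(i) || any(i < 1L | i > N_CORE))
    stop("invalid core position in parameter table")
  if (anyNA(j)) stop("invalid residue code in parameter table")
  if (anyNA(l)) stop("invalid group index in parameter table")
  ng <- nGroups(catalog)
  badl <- l < 0L | l > ng[i]
  if (any(badl))
    stop("unknown group label(s) for their position: ",
         paste(sprintf("(i=%d, l=%s)", i[badl], lraw[badl]),
               collapse = ", "))
  key <- paste(i, j, l)
  if (anyDuplicated(key))
    stop("duplicate parameter entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  beta <- .zeroBeta(catalog)
  for (r in seq_along(i)) beta[[i[r]]][j[r], l[r] + 1L] <- v[r]
  new("ModelParams", catalog = catalog, beta = beta, kT = kT,
      l1Bound = l1Bound, trainingAllotypes = catalog@panel,
      metadata = list(source = basename(path)))
}

#' Read peptides from FASTA or plain text
#'
#' @param path FASTA (parsed with Biostrings) or one-sequence-per-line
#'   text.
#' @return named character vector of peptide sequences.
#' @export
readPeptides <- function(path) {
  firstChar <- substr(readLines(path, n = 1L), 1L, 1L)
  if (identical(firstChar, ">")) {
    ss <- Biostrings::readAAStringSet(path)
    setNames(as.character(ss), names(ss))
  } else {
    seqs <- trimws(readLines(path))
    seqs <- seqs[nzchar(seqs)]
    setNames(seqs, sprintf("pep%05d", seq_along(seqs)))
  }
}

#' Export register scores to TSV
#'
#' One row per (peptide, register): columns \code{peptide_id},
#' \code{allotype}, \code{M}, \code{core_seq}, \code{dG_M}, \code{weight},
#' \code{dG_total}, \code{ic50_nM}.
#'
#' @param scores a [RegisterScores-class] or a list of them.
#' @param path output path.
#' @param RT conversion constant for the IC50 column (kcal/mol).
#' @export
writeRegisterScores <- function(scores, path, RT = 0.592) {
  if (methods::is(scores, "RegisterScores")) scores <- list(scores)
  rows <- lapply(scores, function(rs) {
    Ms <- as.integer(names(rs@energies))
    ord <- order(Ms)
    cores <- rs@cores[match(Ms[ord], rs@cores$M), ]
    data.frame(peptide_id = rs@peptideId, allotype = rs@allotype,
               M = Ms[ord], core_seq = cores$core,
               dG_M = unname(rs@energies[ord]),
               weight = unname(rs@weights[ord]),
               dG_total = rs@dG, ic50_nM = affinityToIC50(rs@dG, RT),
               stringsAsFactors = FALSE)
  })
  .writeTSV(do.call(rbind, rows), path)
}

#' Write allotype profiles to JSON
#' @param profiles a named list of [AllotypeProfile-class].
#' @param path output path.
#' @export
writeProfiles <- function(profiles, path) {
  jsonlite::write_json(lapply(profiles, function(p)
    list(name = p@name, membership = p@membership,
         coveredFraction = p@coveredFraction,
         residueFraction = p@residueFraction,
         missingGroups = p@missingGroups)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname writeProfiles
#' @return \code{readProfiles}: named list of [AllotypeProfile-class].
#' @export
readProfiles <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(x, function(p) {
    mg <- p$missingGroups
    mg <- if (is.null(mg) || !length(mg))
      data.frame(core_pos = integer(), resno = integer(),
                 type = character(), stringsAsFactors = FALSE)
    else data.frame(
      core_pos = vapply(mg, function(r) as.integer(r$core_pos), integer(1)),
      resno = vapply(mg, function(r) as.integer(r$resno), integer(1)),
      type = vapply(mg, function(r) as.character(r$type), character(1)),
      stringsAsFactors = FALSE)
    new("AllotypeProfile", name = as.character(p$name),
        membership = lapply(p$membership, function(z)
          as.numeric(unlist(z))),
        coveredFraction = as.numeric(p$coveredFraction),
        residueFraction = as.numeric(p$residueFraction),
        missingGroups = mg)
  })
  setNames(out, vapply(out, function(p) p@name, character(1)))
}

#' Write a specificity profile to TSV
#'
#' The 9 x 20 contribution matrix plus \code{sigma} and \code{range} rows,
#' suitable for bar-plot rendering of per-position specificity.
#'
#' @param sp a [SpecificityProfile-class].
#' @param path output path.
#' @export
writeSpecificityProfile <- function(sp, path) {
  df <- data.frame(position = rownames(sp@contributions),
                   sp@contributions,
                   sigma = sp@sigma, range = sp@range,
                   check.names = FALSE)
  .writeTSV(df, path)
}
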