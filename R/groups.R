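#' Construct a contact map directly from pairs
#'
#' @param pairs data.frame with columns \code{core_pos} (1-9) and
#'   \code{resno}.
#' @param provenance character identifiers of the source structures (or
#'   \code{"supplied"}).
#' @return a [ContactMap-class].
#' @export
contactMap <- function(pairs, provenance = "supplied") {
  pairs <- unique(data.frame(core_pos = as.integer(pairs$core_pos),
                             resno = as.integer(pairs$resno)))
  pairs <- pairs[order(pairs$core_pos, pairs$resno), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactMap", pairs = pairs, provenance = provenance)
}

#' Extract peptide-MHC contacts from complex structures
#'
#' A (core position, MHC residue) pair is a contact when any pair of
#' non-hydrogen atoms is separated by strictly less than \code{cutoff}
#' Angstrom in at least one structure. Results are unioned over structures.
#' MHC residue numbers are translated to the panel alignment numbering via
#' \code{mapping}; residues without a mapping are skipped with a message.
#'
#' @param files character vector of PDB files of peptide-MHC complexes.
#' @param coreResno list (one element per file) of length-9 integer vectors:
#'   the peptide-chain residue numbers of core positions P1..P9.
#' @param peptideChain,mhcChain chain identifiers of the peptide and the MHC
#'   beta chain in the structures (recycled across files).
#' @param mapping \code{NULL} (identity) or a named integer vector
#'   translating structure MHC residue numbers to panel numbering, e.g.
#'   \code{c("9" = 9, "11" = 11)}.
#' @param cutoff heavy-atom distance threshold in Angstrom (strict
#'   inequality; default 4.0).
#' @return a [ContactMap-class].
#' @export
extractContacts <- function(files, coreResno, peptideChain = "C",
                            mhcChain = "B", mapping = NULL, cutoff = 4.0) {
  if (length(coreResno) != length(files))
    stop("coreResno must provide one core annotation per structure")
  peptideChain <- rep_len(peptideChain, length(files))
  mhcChain <- rep_len(mhcChain, length(files))
  allPairs <- list()
  for (s in seq_along(files)) {
    cores <- coreResno[[s]]
    if (is.null(cores) || length(cores) < N_CORE || anyNA(cores))
      stop(sprintf("structure '%s' lacks a complete 9-residue core annotation",
                   files[s]))
    pdb <- bio3d::read.pdb(files[s])
    at <- pdb$atom
    heavy <- !(toupper(trimws(at$elesy)) %in% "H")
    pep <- at[heavy & at$chain == peptideChain[s], , drop = FALSE]
    mhc <- at[heavy & at$chain == mhcChain[s], , drop = FALSE]
    if (!nrow(pep) || !nrow(mhc))
      stop(sprintf("structure '%s': peptide or MHC chain not found", files[s]))
    mx <- as.matrix(mhc[, c("x", "y", "z")])
    for (i in seq_len(N_CORE)) {
      pa <- pep[pep$resno == cores[i], c("x", "y", "z"), drop = FALSE]
      if (!nrow(pa)) next
      # nearest heavy-atom distance from each MHC atom to this core residue
      d2min <- rep(Inf, nrow(mx))
      for (r in seq_len(nrow(pa))) {
        d2 <- (mx[, 1] - pa[r, 1])^2 + (mx[, 2] - pa[r, 2])^2 +
          (mx[, 3] - pa[r, 3])^2
        d2min <- pmin(d2min, d2)
      }
      resns <- unique(mhc$resno[d2min < cutoff^2])
      if (!length(resns)) next
      if (!is.null(mapping)) {
        mapped <- mapping[as.character(resns)]
        if (anyNA(mapped)) {
          message(sprintf(
            "structure '%s': skipping unmapped MHC residue(s) %s",
            files[s],
            paste(resns[is.na(mapped)], collapse = ", ")))
          mapped <- mapped[!is.na(mapped)]
        }
        resns <- as.integer(mapped)
      }
      if (length(resns))
        allPairs[[length(allPairs) + 1L]] <-
          data.frame(core_pos = i, resno = resns)
    }
  }
  pairs <- if (length(allPairs)) do.call(rbind, allPairs) else
    data.frame(core_pos = integer(), resno = integer())
  contactMap(pairs, provenance = basename(files))
}

# Occurrence set of a variant: which panel members carry residue `type` at
# position `resno`. Variants are grouped by identical occurrence sets.
.panelChars <- function(panel) {
  if (methods::is(panel, "AAStringSet"))
    panel <- setNames(as.character(panel), names(panel))
  if (!length(panel)) stop("panel must contain at least one sequence")
  if (is.null(names(panel)) || any(!nzchar(names(panel))))
    stop("panel sequences must be named by allotype")
  lapply(panel, .splitSeq)
}

#' Build the residue variant group catalog from an aligned panel
#'
#' At each core position, every (residue number, residue type) variant seen
#' at a contacting MHC residue is assigned an occurrence set: the panel
#' allotypes carrying it. Variants carried by the whole panel form the
#' invariant group l = 0. The remaining variants are partitioned into
#' maximal co-occurring groups: two variants share a group exactly when
#' their occurrence sets are equal, so no two groups at a position have the
#' same occurrence set. Alignment gaps (\code{-}) count as a distinct
#' variant type, so deletions split groups. Group order (by smallest residue
#' number, then type) is deterministic.
#'
#' @param panel named character vector (or \code{Biostrings::AAStringSet})
#'   of aligned MHC beta-chain sequences; residue numbers index alignment
#'   columns.
#' @param contacts a [ContactMap-class].
#' @return a [GroupCatalog-class].
#' @examples
#' cm <- contactMap(data.frame(core_pos = 4, resno = c(11, 13)))
#' panel <- c(A = "xxxxxxxxxxAxCx", B = "xxxxxxxxxxAxCx",
#'            C = "xxxxxxxxxxDxEx")
#' panel <- gsub("x", "G", panel)
#' buildGroupCatalog(panel, cm)
#' @export
buildGroupCatalog <- function(panel, contacts) {
  chars <- .panelChars(panel)
  if (!length(chars)) stop("panel must contain at least one sequence")
  pnames <- names(chars)
  pairs <- contacts@pairs
  maxres <- if (nrow(pairs)) max(pairs$resno) else 0L
  short <- vapply(chars, length, integer(1)) < maxres
  if (any(short))
    stop("panel sequence(s) do not cover all contact residues: ",
         paste(pnames[short], collapse = ", "))
  groups <- rep(list(list()), N_CORE)
  invariant <- rep(list(data.frame(resno = integer(), type = character(),
                                   stringsAsFactors = FALSE)), N_CORE)
  for (i in seq_len(N_CORE)) {
    resns <- sort(unique(pairs$resno[pairs$core_pos == i]))
    if (!length(resns)) next
    vres <- integer(); vtype <- character(); vocc <- character()
    for (rn in resns) {
      types <- vapply(chars, `[`, character(1), rn)
      for (tp in sort(unique(types))) {
        occ <- pnames[types == tp]
        vres <- c(vres, rn); vtype <- c(vtype, tp)
        vocc <- c(vocc, paste(sort(occ), collapse = "\r"))
      }
    }
    allOcc <- paste(sort(pnames), collapse = "\r")
    inv <- vocc == allOcc
    invariant[[i]] <- data.frame(resno = vres[inv], type = vtype[inv],
                                 stringsAsFactors = FALSE)
    if (any(!inv)) {
      vres <- vres[!inv]; vtype <- vtype[!inv]; vocc <- vocc[!inv]
      keys <- unique(vocc)
      glist <- lapply(keys, function(k)
        data.frame(resno = vres[vocc == k], type = vtype[vocc == k],
                   stringsAsFactors = FALSE))
      ord <- order(vapply(glist, function(g) min(g$resno), integer(1)),
                   vapply(glist, function(g)
                     g$type[which.min(g$resno)], character(1)))
      groups[[i]] <- glist[ord]
    }
  }
  new("GroupCatalog", groups = groups, invariant = invariant,
      panel = pnames, contacts = contacts,
      metadata = list(numbering = "panel alignment columns (1-based)"))
}

#' Profile an MHC allotype sequence against a group catalog
#'
#' Computes the binary group membership z used by prediction: z[i, l] = 1
#' exactly when the sequence carries every variant of group l at core
#' position i (l = 0 is always 1). Variants the sequence carries at
#' polymorphic contacting residues that match no catalog group are reported
#' in \code{missingGroups}; their energy contribution is zero, and coverage
#' fractions quantify how much of the allotype's variation the model
#' accounts for.
#'
#' @param sequence MHC beta-chain sequence aligned to the panel numbering
#'   (a character string or named length-1 character vector).
#' @param catalog a [GroupCatalog-class].
#' @param name allotype name stored in the profile (defaults to the names
#'   attribute of \code{sequence}).
#' @return an [AllotypeProfile-class].
#' @export
profileAllotype <- function(sequence, catalog, name = NULL) {
  if (methods::is(sequence, "AAStringSet")) {
    if (is.null(name)) name <- names(sequence)[1L]
    sequence <- as.character(sequence)[1L]
  }
  if (is.null(name))
    name <- if (!is.null(names(sequence))) names(sequence)[1L] else "allotype"
  chars <- .splitSeq(unname(sequence))
  pairs <- catalog@contacts@pairs
  maxres <- if (nrow(pairs)) max(pairs$resno) else 0L
  if (length(chars) < maxres)
    stop(sprintf(
      "sequence '%s' (length %d) does not cover contact residue %d; it must be aligned to the panel numbering",
      name, length(chars), maxres))
  ng <- nGroups(catalog)
  membership <- vector("list", N_CORE)
  miss <- list()
  nMatchedGroups <- 0L; nMissingVar <- 0L
  nCoveredRes <- 0L; nPolyRes <- 0L
  for (i in seq_len(N_CORE)) {
    z <- c(1, numeric(ng[i]))
    gs <- catalog@groups[[i]]
    for (l in seq_along(gs))
      if (all(chars[gs[[l]]$resno] == gs[[l]]$type)) z[l + 1L] <- 1
    membership[[i]] <- z
    # coverage over polymorphic contacting residues at this position
    polyRes <- sort(unique(unlist(lapply(gs, `[[`, "resno"))))
    matchedHere <- logical(length(gs))
    for (rn in polyRes) {
      tp <- chars[rn]
      if (nrow(catalog@invariant[[i]]) &&
          any(catalog@invariant[[i]]$resno == rn &
              catalog@invariant[[i]]$type == tp))
        next  # residue falls in the invariant set, not polymorphic for it
      nPolyRes <- nPolyRes + 1L
      inGroup <- vapply(gs, function(g)
        any(g$resno == rn & g$type == tp), logical(1))
      if (any(inGroup)) {
        nCoveredRes <- nCoveredRes + 1L
        matchedHere <- matchedHere | inGroup
      } else {
        nMissingVar <- nMissingVar + 1L
        miss[[length(miss) + 1L]] <-
          data.frame(core_pos = i, resno = rn, type = tp,
                     stringsAsFactors = FALSE)
      }
    }
    nMatchedGroups <- nMatchedGroups + sum(matchedHere)
  }
  covG <- if (nMatchedGroups + nMissingVar > 0)
    nMatchedGroups / (nMatchedGroups + nMissingVar) else 1
  covR <- if (nPolyRes > 0) nCoveredRes / nPolyRes else 1
  missing <- if (length(miss)) do.call(rbind, miss) else
    data.frame(core_pos = integer(), resno = integer(), type = character(),
               stringsAsFactors = FALSE)
  new("AllotypeProfile", name = name, membership = membership,
      coveredFraction = covG, residueFraction = covR,
      missingGroups = missing)
}

#' Profile every member of the catalog's own panel
#'
#' @param panel the aligned panel sequences used to build \code{catalog}.
#' @param catalog a [GroupCatalog-class].
#' @return named list of [AllotypeProfile-class] objects.
#' @export
panelProfiles <- function(panel, catalog) {
  chars <- .panelChars(panel)
  out <- lapply(names(chars), function(nm)
    profileAllotype(paste(chars[[nm]], collapse = ""), catalog, name = nm))
  setNames(out, names(chars))
}
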