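# Benchmark-set curation: length/contact/UNK/symmetry filters and
# domain-family deduplication, producing per-entry reports.

#' Candidate benchmark entry
#'
#' One two-chain structure under consideration for the benchmark, with its
#' receptor/peptide chain assignment and the external annotations the filters
#' consume: a domain-family label (ECOD-style) for deduplication, the
#' crystallographic resolution, whether the domain's PDB-range and seq-range
#' annotations agree, and whether the entry carries PTMs or bound ligands
#' near the peptide (such entries are set aside, not rejected).
#'
#' @slot entryId identifier.
#' @slot structure a [PepStructure-class].
#' @slot receptorChain,peptideChain chain ids (distinct).
#' @slot domainLabel family label or `NA`.
#' @slot resolution Angstrom or `NA`.
#' @slot rangeAgreement logical or `NA` (external annotation).
#' @slot ptmLig logical: PTM/ligand set-aside flag (external annotation).
#' @export
setClass("CandidateEntry",
         representation(entryId = "character", structure = "PepStructure",
                        receptorChain = "character",
                        peptideChain = "character",
                        domainLabel = "character", resolution = "numeric",
                        rangeAgreement = "logical", ptmLig = "logical"))

setValidity("CandidateEntry", function(object) {
  if (identical(object@receptorChain, object@peptideChain))
    return("receptor and peptide chains must be distinct")
  TRUE
})

#' @describeIn CandidateEntry constructor
#' @param entryId identifier.
#' @param structure a [PepStructure-class].
#' @param receptorChain,peptideChain chain ids.
#' @param domainLabel,resolution,rangeAgreement,ptmLig annotations.
#' @export
candidateEntry <- function(entryId, structure, receptorChain, peptideChain,
                           domainLabel = NA_character_,
                           resolution = NA_real_, rangeAgreement = NA,
                           ptmLig = FALSE) {
  new("CandidateEntry", entryId = as.character(entryId),
      structure = structure, receptorChain = as.character(receptorChain),
      peptideChain = as.character(peptideChain),
      domainLabel = as.character(domainLabel),
      resolution = as.numeric(resolution),
      rangeAgreement = as.logical(rangeAgreement),
      ptmLig = isTRUE(ptmLig))
}

setMethod("show", "CandidateEntry", function(object) {
  cat(sprintf("CandidateEntry %s: receptor %s / peptide %s, family %s\n",
              object@entryId, object@receptorChain, object@peptideChain,
              object@domainLabel))
  invisible(NULL)
})

entrySeqres <- function(entry, side) {
  cid <- if (side == "receptor") entry@receptorChain else entry@peptideChain
  sr <- chainSeqres(entry@structure, cid)
  if (length(sr)) sr
  else uniqueResidues(chainAtoms(entry@structure, cid))$resname
}

#' Chain-length filter
#'
#' Pass iff the receptor SEQRES is over 30 amino acids long, the peptide
#' SEQRES length is between 4 and 25 amino acids, and at least 3 peptide
#' residues are resolved in the coordinates.
#'
#' @param entry a [CandidateEntry-class].
#' @return logical flag.
#' @export
lengthFilter <- function(entry) {
  recLen <- length(entrySeqres(entry, "receptor"))
  pepLen <- length(entrySeqres(entry, "peptide"))
  pepResolved <- nrow(uniqueResidues(
    chainAtoms(entry@structure, entry@peptideChain)))
  recLen > 30L && pepLen >= 4L && pepLen <= 25L && pepResolved >= 3L
}

#' Peptide-receptor contact filter
#'
#' Pass iff at least `minResidues` peptide residues have any heavy atom
#' within `cutoff` of any receptor heavy atom.
#'
#' @param entry a [CandidateEntry-class].
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @param minResidues minimum contacting peptide residues (default 2).
#' @return logical flag.
#' @export
contactFilter <- function(entry, cutoff = 4.0, minResidues = 2L) {
  countContactingPeptideResidues(entry, cutoff) >= minResidues
}

countContactingPeptideResidues <- function(entry, cutoff) {
  rec <- heavyAtoms(chainAtoms(entry@structure, entry@receptorChain))
  pep <- heavyAtoms(chainAtoms(entry@structure, entry@peptideChain))
  if (!nrow(rec) || !nrow(pep)) return(0L)
  d2 <- crossDist2(atomCoords(pep), atomCoords(rec))
  hit <- rowSums(d2 <= cutoff^2) > 0
  length(unique(paste(pep$resno[hit], pep$inscode[hit])))
}

#' Unknown-residue filter
#'
#' Pass iff no peptide SEQRES entry is annotated `UNK`.
#'
#' @param entry a [CandidateEntry-class].
#' @return logical flag.
#' @export
unkFilter <- function(entry) {
  !any(entrySeqres(entry, "peptide") == "UNK")
}

#' Range-agreement filter
#'
#' Consumes the external annotation of whether the receptor domain's
#' PDB-range and seq-range fields agree; entries without the annotation pass.
#'
#' @param entry a [CandidateEntry-class].
#' @return logical flag.
#' @export
rangeAgreementFilter <- function(entry) {
  is.na(entry@rangeAgreement) || isTRUE(entry@rangeAgreement)
}

# orthogonalization matrix: fractional -> cartesian, for cell
# (a, b, c, alpha, beta, gamma)
orthMatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c_ * cos(be),
           0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c_ * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Fraction of peptide residues in contact with crystal symmetry mates
#'
#' Applies every symmetry operator of the entry combined with lattice
#' translations in \{-1,0,1\}^3 to the asymmetric unit (skipping the identity
#' image) and returns the fraction of resolved peptide residues having any
#' heavy atom within `contactCutoff` of any symmetry-mate atom. Peptides
#' whose bound conformation is propped up by such crystal contacts are not
#' faithful examples of the binary interaction.
#'
#' @param entry a [CandidateEntry-class]; its structure must carry a cell
#'   and symmetry operators (otherwise 0 is returned with a warning).
#' @param contactCutoff heavy-atom cutoff in Angstrom (default 4.0).
#' @param latticeRange integer range of lattice translations (default 1).
#' @return fraction in \[0,1\].
#' @export
symmetryContactFraction <- function(entry, contactCutoff = 4.0,
                                    latticeRange = 1L) {
  st <- entry@structure
  if (!length(st@cell) || !length(st@symOps)) {
    warning("entry ", entry@entryId,
            ": no cell or symmetry operators; fraction 0 assumed")
    return(0)
  }
  if (any(st@cell[1:3] <= 0)) stop("invalid unit cell")
  O <- orthMatrix(st@cell)
  Fm <- solve(O)
  au <- heavyAtoms(st@atoms)
  auFrac <- atomCoords(au) %*% t(Fm)
  pep <- heavyAtoms(chainAtoms(st, entry@peptideChain))
  pepXyz <- atomCoords(pep)
  shifts <- as.matrix(expand.grid(-latticeRange:latticeRange,
                                  -latticeRange:latticeRange,
                                  -latticeRange:latticeRange))
  resKey <- paste(pep$resno, pep$inscode)
  nRes <- length(unique(resKey))
  inContact <- logical(nrow(pep))
  for (op in st@symOps) {
    opFrac <- auFrac %*% t(op$R) +
      matrix(op$t, nrow(auFrac), 3, byrow = TRUE)
    isIdOp <- max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9
    for (s in seq_len(nrow(shifts))) {
      shift <- as.numeric(shifts[s, ])
      if (isIdOp && all(shift == 0)) next   # the reference copy itself
      mateXyz <- sweep(opFrac, 2, shift, "+") %*% t(O)
      d2 <- crossDist2(pepXyz, mateXyz)
      inContact <- inContact | rowSums(d2 <= contactCutoff^2) > 0
    }
  }
  length(unique(resKey[inContact])) / nRes
}

#' Crystal-symmetry contact filter
#'
#' Fail iff at least `threshold` (default 20%) of the peptide residues are in
#' contact with symmetry mates.
#'
#' @inheritParams symmetryContactFraction
#' @param threshold rejection threshold on the contact fraction
#'   (default 0.20; boundary inclusive).
#' @return logical flag (TRUE = pass).
#' @export
symmetryFilter <- function(entry, threshold = 0.20, contactCutoff = 4.0) {
  symmetryContactFraction(entry, contactCutoff) < threshold
}

#' Deduplicate entries by domain-family label
#'
#' Keeps one entry per domain label: the best (lowest) resolution, ties
#' broken by lexicographically smallest entry id. Entries whose label appears
#' in `exclude` are removed entirely (e.g. families already represented in a
#' calibration set).
#'
#' @param entries list of [CandidateEntry-class] objects, all labelled.
#' @param exclude character vector of labels to drop.
#' @return the surviving entries (original order).
#' @export
dedupeByDomain <- function(entries, exclude = character(0)) {
  labels <- vapply(entries, function(e) e@domainLabel, character(1))
  if (anyNA(labels)) {
    ids <- vapply(entries[is.na(labels)], function(e) e@entryId,
                  character(1))
    stop("entries without domain label: ", paste(ids, collapse = ", "))
  }
  keep <- logical(length(entries))
  for (lab in setdiff(unique(labels), exclude)) {
    idx <- which(labels == lab)
    resol <- vapply(entries[idx], function(e) e@resolution, numeric(1))
    resol[is.na(resol)] <- Inf
    ids <- vapply(entries[idx], function(e) e@entryId, character(1))
    best <- idx[order(resol, ids)][1]
    keep[best] <- TRUE
  }
  entries[keep]
}

#' Run the full curation filter chain
#'
#' Applies, in order: length, UNK, range-agreement, contact, and
#' crystal-symmetry filters, then domain deduplication on the survivors.
#' Entries flagged `ptmLig` that pass every filter are placed in a set-aside
#' list rather than the accepted benchmark. Every entry receives a
#' per-filter report; the filters are independent predicates, so the
#' accepted set does not depend on their order.
#'
#' @param entries list of [CandidateEntry-class] objects.
#' @param excludeFamilies domain labels to remove during deduplication.
#' @param contactCutoff,minContactResidues contact-filter parameters.
#' @param symmetryThreshold symmetry-filter threshold (default 0.20).
#' @return list with `accepted` (entries), `setAside` (PTM/ligand entries),
#'   and `reports` (data.frame: one row per entry with per-filter flags,
#'   `accepted`, and `details`).
#' @export
curateEntries <- function(entries, excludeFamilies = character(0),
                          contactCutoff = 4.0, minContactResidues = 2L,
                          symmetryThreshold = 0.20) {
  reports <- lapply(entries, function(e) {
    flags <- c(
      length = lengthFilter(e),
      unk = unkFilter(e),
      range_agreement = rangeAgreementFilter(e),
      contact = contactFilter(e, contactCutoff, minContactResidues),
      symmetry = suppressWarnings(
        symmetryFilter(e, symmetryThreshold, contactCutoff)))
    failed <- names(flags)[!flags]
    data.frame(entry_id = e@entryId, t(flags),
               pass_filters = all(flags), ptm_lig = e@ptmLig,
               details = if (length(failed))
                 paste("failed:", paste(failed, collapse = ","))
               else "pass",
               stringsAsFactors = FALSE)
  })
  reports <- do.call(rbind, reports)
  passing <- entries[reports$pass_filters]
  setAside <- Filter(function(e) e@ptmLig, passing)
  candidates <- Filter(function(e) !e@ptmLig, passing)
  accepted <- dedupeByDomain(candidates, exclude = excludeFamilies)
  keptIds <- vapply(accepted, function(e) e@entryId, character(1))
  reports$deduped <- reports$pass_filters & !reports$ptm_lig &
    !reports$entry_id %in% keptIds
  reports$accepted <- reports$pass_filters & !reports$ptm_lig &
    reports$entry_id %in% keptIds
  list(accepted = accepted, setAside = setAside, reports = reports)
}
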