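# Predictor contract, splitting of fused models, failure detection.

#' Validate a model against the predictor contract
#'
#' A predictor adapter is any function `f(query, seed)` returning a
#' [PredictedModel-class]; it must be deterministic given `(query, seed)`.
#' This checker enforces the structural side of the contract: linked-mode
#' models are a single chain of length receptor + linker + peptide,
#' separate-chain models are two chains matching the two sequence lengths,
#' and confidence values lie in \[0,1\].
#'
#' @param model a [PredictedModel-class].
#' @return `model`, invisibly; errors on contract violation.
#' @export
checkPredictedModel <- function(model) {
  stopifnot(is(model, "PredictedModel"))
  q <- model@query
  res <- uniqueResidues(model@structure@atoms)
  if (q@linkage == "linked") {
    if (length(chainIds(model@structure)) != 1L)
      stop("linked-mode model must have exactly one chain")
    if (nrow(res) != nchar(q@fusedSeq))
      stop("linked-mode model has ", nrow(res), " residues; query expects ",
           nchar(q@fusedSeq))
  } else if (q@linkage == "separate") {
    cids <- chainIds(model@structure)
    if (length(cids) != 2L)
      stop("separate-chain model must have exactly two chains")
    lens <- vapply(cids, function(cid)
      nrow(uniqueResidues(chainAtoms(model@structure, cid))), integer(1))
    if (!identical(unname(lens),
                   c(nchar(q@receptorSeq), nchar(q@peptideSeq))))
      stop("separate-chain model lengths (", paste(lens, collapse = ", "),
           ") do not match query (", nchar(q@receptorSeq), ", ",
           nchar(q@peptideSeq), ")")
  } else stop("unknown linkage: ", q@linkage)
  invisible(model)
}

#' Split a fused model into receptor and peptide
#'
#' For a linked-mode model of R + L + P residues, the first R residues become
#' receptor chain A, the middle L linker residues are discarded (they are
#' never scored), and the last P residues become peptide chain B. Residue
#' numbers restart at 1 in each chain and `seqidx` indexes each partner's own
#' sequence. Separate-chain models pass through with their two chains mapped
#' to A/B and nothing discarded. Coordinates are never transformed.
#'
#' @param model a [PredictedModel-class].
#' @return a [SplitComplex-class]; peptide-residue confidence is carried in
#'   the atoms' `bfactor` column.
#' @export
splitFusedModel <- function(model) {
  checkPredictedModel(model)
  q <- model@query
  st <- model@structure
  if (q@linkage == "separate") {
    cids <- chainIds(st)
    rec <- renumberChain(chainAtoms(st, cids[1]), "A")
    pep <- renumberChain(chainAtoms(st, cids[2]), "B")
    return(SplitComplex(rec, pep,
                        receptorSeqres = oneToThree(q@receptorSeq),
                        peptideSeqres = oneToThree(q@peptideSeq),
                        linkerDiscarded = 0L))
  }
  atoms <- chainAtoms(st, chainIds(st)[1])
  res <- uniqueResidues(atoms)
  R <- nchar(q@receptorSeq); L <- q@linkerLength; P <- nchar(q@peptideSeq)
  if (nrow(res) != R + L + P)
    stop("fused model has ", nrow(res), " residues, expected ", R + L + P)
  key <- paste(atoms$resno, atoms$inscode)
  resIdx <- match(key, paste(res$resno, res$inscode))  # 1-based residue rank
  rec <- renumberChain(atoms[resIdx <= R, , drop = FALSE], "A")
  pep <- renumberChain(atoms[resIdx > R + L, , drop = FALSE], "B")
  SplitComplex(rec, pep,
               receptorSeqres = oneToThree(q@receptorSeq),
               peptideSeqres = oneToThree(q@peptideSeq),
               linkerDiscarded = as.integer(L))
}

renumberChain <- function(atoms, chainId) {
  res <- uniqueResidues(atoms)
  key <- paste(atoms$resno, atoms$inscode)
  rank <- match(key, paste(res$resno, res$inscode))
  atoms$chain <- chainId
  atoms$resno <- rank
  atoms$inscode <- ""
  atoms$seqidx <- rank - 1L
  rownames(atoms) <- NULL
  atoms
}

oneToThree <- function(seq) {
  letters1 <- strsplit(seq, "")[[1]]
  three <- names(STANDARD_AA3)[match(letters1, STANDARD_AA3)]
  if (anyNA(three)) stop("non-standard letters in sequence: ", seq)
  three
}

#' Detect a failed model (peptide pointing out into space)
#'
#' A characteristic failure mode of linker-based docking is a model in which
#' the peptide does not interact with the receptor at all but points out into
#' space. A model is flagged as failed when no peptide heavy atom lies within
#' `contactCutoff` of any receptor heavy atom.
#'
#' @param split a [SplitComplex-class].
#' @param contactCutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return logical flag.
#' @export
detectFailure <- function(split, contactCutoff = 4.0) {
  stopifnot(is(split, "SplitComplex"))
  rec <- heavyAtoms(split@receptor); pep <- heavyAtoms(split@peptide)
  if (!nrow(rec) || !nrow(pep)) stop("empty chain in split complex")
  !anyWithin(atomCoords(rec), atomCoords(pep), contactCutoff)
}

heavyAtoms <- function(atoms) {
  atoms[atoms$element != "H", , drop = FALSE]
}

#' Write a split complex as a two-chain PDB file
#'
#' @param split a [SplitComplex-class].
#' @param path output file.
#' @param entryId identifier for the written entry.
#' @return `path`, invisibly.
#' @export
writeSplitComplex <- function(split, path, entryId = "complex") {
  stopifnot(is(split, "SplitComplex"))
  st <- splitToStructure(split, entryId)
  writeStructurePDB(st, path)
}

splitToStructure <- function(split, entryId = "complex",
                             cell = numeric(0), symOps = list()) {
  atoms <- rbind(split@receptor, split@peptide)
  rownames(atoms) <- NULL
  seqres <- list()
  if (length(split@receptorSeqres)) seqres$A <- split@receptorSeqres
  if (length(split@peptideSeqres)) seqres$B <- split@peptideSeqres
  PepStructure(entryId, atoms, seqres = seqres, cell = cell,
               symOps = symOps)
}

#' Split a two-chain native structure into a receptor-peptide complex
#'
#' @param x a [PepStructure-class] with at least two chains.
#' @param receptorChain,peptideChain chain identifiers.
#' @return a [SplitComplex-class].
#' @export
asSplitComplex <- function(x, receptorChain, peptideChain) {
  stopifnot(is(x, "PepStructure"))
  rec <- chainAtoms(x, receptorChain); pep <- chainAtoms(x, peptideChain)
  rec$chain <- "A"; pep$chain <- "B"
  SplitComplex(rec, pep,
               receptorSeqres = chainSeqres(x, receptorChain),
               peptideSeqres = chainSeqres(x, peptideChain),
               linkerDiscarded = 0L)
}
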