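#' @import methods
NULL

# Atom tables are plain data.frames with a fixed column contract, shared by
# every class below:
#   chain   character  chain identifier
#   resno   integer    author residue number
#   inscode character  insertion code ("" if none)
#   resname character  3-letter residue name
#   seqidx  integer    0-based index into the chain's SEQRES, NA if unknown
#   atom    character  PDB atom name (e.g. "CA")
#   element character  element symbol
#   x,y,z   numeric    coordinates, Angstrom
#   occ     numeric    occupancy
#   bfactor numeric    B-factor (carries pLDDT in predicted models)
#   altloc  character  alternate-location id ("" if none)

ATOM_COLS <- c("chain", "resno", "inscode", "resname", "seqidx", "atom",
               "element", "x", "y", "z", "occ", "bfactor", "altloc")

emptyAtomTable <- function() {
  data.frame(chain = character(), resno = integer(), inscode = character(),
             resname = character(), seqidx = integer(), atom = character(),
             element = character(), x = numeric(), y = numeric(),
             z = numeric(), occ = numeric(), bfactor = numeric(),
             altloc = character(), stringsAsFactors = FALSE)
}

checkAtomTable <- function(df, what = "atoms") {
  msgs <- character()
  missing <- setdiff(ATOM_COLS, names(df))
  if (length(missing))
    msgs <- c(msgs, sprintf("%s lacks columns: %s", what,
                            paste(missing, collapse = ", ")))
  else {
    if (nrow(df) && !all(is.finite(c(df$x, df$y, df$z))))
      msgs <- c(msgs, sprintf("%s has non-finite coordinates", what))
    occ <- df$occ[!is.na(df$occ)]
    if (length(occ) && (any(occ < 0) || any(occ > 1 + 1e-9)))
      msgs <- c(msgs, sprintf("%s has occupancy outside [0,1]", what))
  }
  msgs
}

#' Protein structure with SEQRES and crystal symmetry
#'
#' Container for one structure (native complex or predicted model): a flat
#' atom table plus per-chain SEQRES sequences, the unit cell, and the crystal
#' symmetry operators in fractional coordinates.
#'
#' @slot entryId single identifier string.
#' @slot atoms atom table (see package internals for the column contract).
#' @slot seqres named list, one character vector of 3-letter residue codes per
#'   chain; a chain may be absent when the source file had no SEQRES.
#' @slot cell numeric(6) unit-cell lengths (Angstrom) and angles (degrees), or
#'   numeric(0) when unknown.
#' @slot symOps list of symmetry operators, each `list(R = 3x3 matrix,
#'   t = numeric(3))` acting on fractional coordinates; empty when unknown.
#'
#' @seealso [readStructure()], [chainIds()], [chainAtoms()]
#' @export
setClass("PepStructure",
         representation(entryId = "character", atoms = "data.frame",
                        seqres = "list", cell = "numeric", symOps = "list"))

setValidity("PepStructure", function(object) {
  msgs <- checkAtomTable(object@atoms)
  if (length(object@entryId) != 1L)
    msgs <- c(msgs, "entryId must be a single string")
  if (length(object@cell) && length(object@cell) != 6L)
    msgs <- c(msgs, "cell must have 6 elements (a, b, c, alpha, beta, gamma)")
  if (length(object@symOps)) {
    ok <- vapply(object@symOps, function(op) {
      is.list(op) && is.matrix(op$R) && all(dim(op$R) == c(3L, 3L)) &&
        length(op$t) == 3L
    }, logical(1))
    if (!all(ok))
      msgs <- c(msgs, "each symOp must be list(R = 3x3 matrix, t = numeric(3))")
    else {
      isIdentity <- vapply(object@symOps, function(op) {
        max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9
      }, logical(1))
      if (!any(isIdentity))
        msgs <- c(msgs, "symOps must include the identity operator")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PepStructure construct a structure object
#' @param entryId identifier string.
#' @param atoms atom table.
#' @param seqres named list of 3-letter-code vectors.
#' @param cell numeric(6) or numeric(0).
#' @param symOps list of fractional-coordinate operators.
#' @export
PepStructure <- function(entryId, atoms, seqres = list(), cell = numeric(0),
                         symOps = list()) {
  new("PepStructure", entryId = as.character(entryId), atoms = atoms,
      seqres = seqres, cell = as.numeric(cell), symOps = symOps)
}

#' Receptor-peptide complex split into its two partners
#'
#' The evaluation unit of every metric: one receptor chain and one peptide
#' chain, each an atom table, plus the SEQRES codes each chain derives from.
#' For models produced from a fused poly-Gly query, `linkerDiscarded` records
#' how many linker residues were dropped during splitting.
#'
#' @slot receptor atom table of the receptor chain.
#' @slot peptide atom table of the peptide chain.
#' @slot receptorSeqres character vector of 3-letter codes (may be empty).
#' @slot peptideSeqres character vector of 3-letter codes (may be empty).
#' @slot linkerDiscarded integer count of discarded linker residues.
#' @seealso [splitFusedModel()], [evaluateComplex()]
#' @export
setClass("SplitComplex",
         representation(receptor = "data.frame", peptide = "data.frame",
                        receptorSeqres = "character",
                        peptideSeqres = "character",
                        linkerDiscarded = "integer"))

setValidity("SplitComplex", function(object) {
  msgs <- c(checkAtomTable(object@receptor, "receptor"),
            checkAtomTable(object@peptide, "peptide"))
  if (length(object@linkerDiscarded) != 1L || object@linkerDiscarded < 0L)
    msgs <- c(msgs, "linkerDiscarded must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SplitComplex construct a split complex
#' @param receptor,peptide atom tables.
#' @param receptorSeqres,peptideSeqres 3-letter-code vectors.
#' @param linkerDiscarded number of linker residues dropped.
#' @export
SplitComplex <- function(receptor, peptide, receptorSeqres = character(0),
                         peptideSeqres = character(0), linkerDiscarded = 0L) {
  new("SplitComplex", receptor = receptor, peptide = peptide,
      receptorSeqres = as.character(receptorSeqres),
      peptideSeqres = as.character(peptideSeqres),
      linkerDiscarded = as.integer(linkerDiscarded))
}

#' Predictor input: receptor and peptide sequences plus protocol settings
#'
#' A docking query in one of two linkage modes. In `linked` mode the two
#' sequences are fused through a poly-glycine linker into a single chain, in
#' the order receptor--linker--peptide (N to C terminus), so that a
#' monomer-folding predictor models the complex as one chain. In `separate`
#' mode the two sequences are presented as two records.
#'
#' @slot receptorSeq one-letter receptor sequence.
#' @slot peptideSeq one-letter peptide sequence.
#' @slot linkage `"linked"` or `"separate"`.
#' @slot linkerLength number of glycines in the linker (linked mode).
#' @slot fusedSeq the fused single-chain sequence (linked mode), else `NA`.
#' @slot config a `RunConfig`-style named list (see [runConfig()]), possibly
#'   empty.
#' @seealso [buildLinkedQuery()], [buildSeparateQuery()],
#'   [buildPolyAlaVariant()]
#' @export
setClass("DockingQuery",
         representation(receptorSeq = "character", peptideSeq = "character",
                        linkage = "character", linkerLength = "integer",
                        fusedSeq = "character", config = "list"))

setValidity("DockingQuery", function(object) {
  msgs <- character()
  if (!nzchar(object@receptorSeq) || !nzchar(object@peptideSeq))
    msgs <- c(msgs, "receptor and peptide sequences must be non-empty")
  if (!object@linkage %in% c("linked", "separate"))
    msgs <- c(msgs, "linkage must be 'linked' or 'separate'")
  if (object@linkage == "linked") {
    expect <- paste0(object@receptorSeq,
                     strrep("G", object@linkerLength), object@peptideSeq)
    if (is.na(object@fusedSeq) || !identical(object@fusedSeq, expect))
      msgs <- c(msgs,
                "fusedSeq must equal receptor + G-linker + peptide")
  }
  if (length(msgs)) msgs else TRUE
})

#' Predicted model: structure, originating query, per-residue confidence
#'
#' @slot structure a [PepStructure-class]: one chain in linked mode, two
#'   chains in separate mode.
#' @slot query the [DockingQuery-class] the model answers.
#' @slot plddt numeric per-residue confidence in \[0,1\], ordered as the
#'   residues of the structure.
#' @seealso [mockPredictor()], [splitFusedModel()]
#' @export
setClass("PredictedModel",
         representation(structure = "PepStructure", query = "DockingQuery",
                        plddt = "numeric"))

setValidity("PredictedModel", function(object) {
  msgs <- character()
  n <- nrow(uniqueResidues(object@structure@atoms))
  if (length(object@plddt) != n)
    msgs <- c(msgs, sprintf("plddt length %d != residue count %d",
                            length(object@plddt), n))
  if (length(object@plddt) &&
      (min(object@plddt) < 0 || max(object@plddt) > 1))
    msgs <- c(msgs, "plddt values must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Interface residue sets under the C-beta 8 Angstrom rule
#'
#' Residue index sets (0-based SEQRES indices) on the peptide and receptor
#' sides whose C-beta atom (C-alpha for glycine) lies within `cutoff` of a
#' cross-chain C-beta/C-alpha. Always derived from the native complex.
#'
#' @slot peptideIf integer vector of peptide seqres indices.
#' @slot receptorIf integer vector of receptor seqres indices.
#' @slot cutoff distance cutoff in Angstrom (default 8.0).
#' @seealso [defineInterface()]
#' @export
setClass("InterfaceDefinition",
         representation(peptideIf = "integer", receptorIf = "integer",
                        cutoff = "numeric"))

setValidity("InterfaceDefinition", function(object) {
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    return("cutoff must be a single positive number")
  TRUE
})

# ---- basic accessors -------------------------------------------------------

#' Chain identifiers of a structure
#' @param x a [PepStructure-class].
#' @return character vector of chain ids, in order of first appearance.
#' @export
chainIds <- function(x) {
  stopifnot(is(x, "PepStructure"))
  unique(x@atoms$chain)
}

#' Atom table of one chain
#' @param x a [PepStructure-class].
#' @param chainId chain identifier.
#' @return the atom table restricted to that chain.
#' @export
chainAtoms <- function(x, chainId) {
  stopifnot(is(x, "PepStructure"))
  if (!chainId %in% x@atoms$chain)
    stop("chain '", chainId, "' not present in structure ", x@entryId)
  x@atoms[x@atoms$chain == chainId, , drop = FALSE]
}

#' SEQRES codes of one chain
#' @inheritParams chainAtoms
#' @return character vector of 3-letter codes (empty if no SEQRES was read).
#' @export
chainSeqres <- function(x, chainId) {
  stopifnot(is(x, "PepStructure"))
  sr <- x@seqres[[chainId]]
  if (is.null(sr)) character(0) else sr
}

#' @describeIn chainIds entry identifier
#' @export
entryId <- function(x) {
  stopifnot(is(x, "PepStructure"))
  x@entryId
}

#' One row per resolved residue of an atom table
#'
#' @param atoms an atom table.
#' @return data.frame with one row per (chain, resno, inscode) in file order,
#'   carrying `chain`, `resno`, `inscode`, `resname`, `seqidx`.
#' @export
uniqueResidues <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$inscode, sep = "|")
  first <- !duplicated(key)
  atoms[first, c("chain", "resno", "inscode", "resname", "seqidx"),
        drop = FALSE]
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "PepStructure", function(object) {
  res <- uniqueResidues(object@atoms)
  cat(sprintf("PepStructure '%s': %d chain(s), %d residues, %d atoms\n",
              object@entryId, length(chainIds(object)), nrow(res),
              nrow(object@atoms)))
  for (cid in chainIds(object)) {
    nres <- sum(res$chain == cid)
    nsr <- length(chainSeqres(object, cid))
    cat(sprintf("  chain %s: %d resolved / %s SEQRES residues\n", cid, nres,
                if (nsr) nsr else "no"))
  }
  if (length(object@cell))
    cat(sprintf("  cell: %s; %d symmetry operator(s)\n",
                paste(format(object@cell, digits = 4), collapse = " "),
                length(object@symOps)))
  invisible(NULL)
})

setMethod("show", "SplitComplex", function(object) {
  cat(sprintf(
    "SplitComplex: receptor %d res / peptide %d res (%d linker discarded)\n",
    nrow(uniqueResidues(object@receptor)),
    nrow(uniqueResidues(object@peptide)), object@linkerDiscarded))
  invisible(NULL)
})

setMethod("show", "DockingQuery", function(object) {
  cat(sprintf("DockingQuery [%s]: receptor %d aa, peptide %d aa",
              object@linkage, nchar(object@receptorSeq),
              nchar(object@peptideSeq)))
  if (object@linkage == "linked")
    cat(sprintf(", fused %d aa (%d-Gly linker)", nchar(object@fusedSeq),
                object@linkerLength))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "PredictedModel", function(object) {
  cat(sprintf("PredictedModel [%s query]: %d residues, mean pLDDT %.2f\n",
              object@query@linkage, length(object@plddt),
              mean(object@plddt)))
  invisible(NULL)
})

setMethod("show", "InterfaceDefinition", function(object) {
  cat(sprintf(
    "InterfaceDefinition (cutoff %.1f A): %d peptide + %d receptor residues\n",
    object@cutoff, length(object@peptideIf), length(object@receptorIf)))
  invisible(NULL)
})

#' @describeIn InterfaceDefinition peptide-side residue indices
#' @param x an `InterfaceDefinition`.
#' @export
peptideInterface <- function(x) {
  stopifnot(is(x, "InterfaceDefinition")); x@peptideIf
}

#' @describeIn InterfaceDefinition receptor-side residue indices
#' @export
receptorInterface <- function(x) {
  stopifnot(is(x, "InterfaceDefinition")); x@receptorIf
}

#' @describeIn SplitComplex receptor atom table
#' @param x a `SplitComplex`.
#' @export
receptorAtoms <- function(x) {
  stopifnot(is(x, "SplitComplex")); x@receptor
}

#' @describeIn SplitComplex peptide atom table
#' @export
peptideAtoms <- function(x) {
  stopifnot(is(x, "SplitComplex")); x@peptide
}
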