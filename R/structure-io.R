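# Reading and writing PDB / mmCIF / FASTA.
#
# Atom records are parsed with bio3d (read.pdb / read.cif); the few header
# categories bio3d does not expose -- SEQRES sequences in mmCIF, the CRYST1
# cell, and the crystallographic symmetry operator lists -- are handled by the
# small routines below. Symmetry operators are carried everywhere as
# fractional-coordinate (R, t) pairs and serialised as standard
# "X,Y+1/2,-Z"-style strings.

STANDARD_AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# parent-residue mapping for common non-standard residues seen inside chains
NONSTANDARD_PARENT <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                        CSO = "CYS", CME = "CYS", CSX = "CYS", OCS = "CYS",
                        HYP = "PRO", MLY = "LYS", M3L = "LYS", KCX = "LYS",
                        ALY = "LYS", PCA = "GLU", HIC = "HIS", NEP = "HIS",
                        FME = "MET", MLE = "LEU", AIB = "ALA", DAL = "ALA",
                        SEC = "CYS", PYL = "LYS")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a structure from PDB or mmCIF
#'
#' Parses atom records (via bio3d), SEQRES sequences, the unit cell and the
#' crystallographic symmetry operators into a [PepStructure-class]. Alternate
#' locations are reduced to the highest-occupancy conformer (ties broken
#' alphabetically); only the first NMR model is kept.
#'
#' Each resolved residue is assigned a 0-based `seqidx` into its chain's
#' SEQRES by constant-offset matching of residue numbers against the SEQRES
#' codes; when the file carries no SEQRES, residue numbers relative to the
#' first resolved residue are used.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return a [PepStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  parsed <- tryCatch(
    if (format == "pdb") parsePdb(path, lines) else parseCif(path, lines),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  atoms <- dropAltlocs(parsed$atoms)
  atoms <- assignSeqidx(atoms, parsed$seqres)
  PepStructure(entryId = parsed$entryId, atoms = atoms,
               seqres = parsed$seqres, cell = parsed$cell,
               symOps = parsed$symOps)
}

parsePdb <- function(path, lines) {
  # rm.alt = FALSE: altloc reduction is ours (highest occupancy, not "A")
  utils::capture.output(
    pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    inscode = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resname = as.character(a$resid), seqidx = NA_integer_,
    atom = as.character(a$elety),
    element = ifelse(is.na(a$elesy), guessElement(a$elety),
                     as.character(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), bfactor = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    stringsAsFactors = FALSE)
  seqres <- list()
  if (!is.null(pdb$seqres) && length(pdb$seqres))
    seqres <- split(unname(pdb$seqres), names(pdb$seqres))
  cell <- parseCryst1(lines)
  symOps <- parseRemark290(lines)
  hdr <- grep("^HEADER", lines, value = TRUE)
  entryId <- if (length(hdr)) trimws(substr(hdr[1], 63, 66)) else ""
  if (!nzchar(entryId))
    entryId <- sub("\\.[^.]*$", "", basename(path))
  list(entryId = entryId, atoms = atoms, seqres = seqres, cell = cell,
       symOps = symOps)
}

parseCif <- function(path, lines) {
  cif <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  a <- cif$atom
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    inscode = ifelse(is.na(a$insert) | a$insert == "?", "",
                     as.character(a$insert)),
    resname = as.character(a$resid), seqidx = NA_integer_,
    atom = as.character(a$elety),
    element = ifelse(is.na(a$elesy), guessElement(a$elety),
                     as.character(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), bfactor = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt) | a$alt %in% c(".", "?"), "",
                    as.character(a$alt)),
    stringsAsFactors = FALSE)
  cell <- cifCell(lines)
  symOps <- cifSymOps(lines)
  seqres <- cifSeqres(lines)
  dataLine <- grep("^data_", lines, value = TRUE)
  entryId <- if (length(dataLine)) sub("^data_", "", dataLine[1]) else
    sub("\\.[^.]*$", "", basename(path))
  list(entryId = entryId, atoms = atoms, seqres = seqres, cell = cell,
       symOps = symOps)
}

guessElement <- function(atomName) {
  e <- sub("^[0-9]*", "", as.character(atomName))
  substr(e, 1, 1)
}

# keep, per atom name within a residue, the highest-occupancy altloc
# (ties: alphabetically first altloc id)
dropAltlocs <- function(atoms) {
  if (!nrow(atoms) || all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$inscode, atoms$atom,
               sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  # restore file order
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

# constant-offset match of resolved residue numbers against SEQRES codes
assignSeqidx <- function(atoms, seqres) {
  if (!nrow(atoms)) return(atoms)
  for (cid in unique(atoms$chain)) {
    sel <- atoms$chain == cid
    resno <- atoms$resno[sel]
    sr <- seqres[[cid]]
    if (is.null(sr) || !length(sr)) {
      atoms$seqidx[sel] <- resno - min(resno)
      next
    }
    res <- unique(data.frame(resno = resno,
                             resname = atoms$resname[sel]))
    n <- length(sr)
    offsets <- seq(1L - min(res$resno), n - max(res$resno))
    best <- NA_integer_; bestScore <- -1L
    for (d in offsets) {
      score <- sum(sr[res$resno + d] == res$resname)
      if (score > bestScore) { bestScore <- score; best <- d }
      if (score == nrow(res)) break
    }
    if (is.na(best) || bestScore == 0L) {
      warning("chain ", cid, ": resolved residues do not match SEQRES; ",
              "seqidx left unset")
      atoms$seqidx[sel] <- NA_integer_
    } else {
      atoms$seqidx[sel] <- resno + best - 1L   # 0-based
    }
  }
  atoms
}

# ---- PDB header records ----------------------------------------------------

parseCryst1 <- function(lines) {
  ln <- grep("^CRYST1", lines, value = TRUE)
  if (!length(ln)) return(numeric(0))
  f <- function(i, j) as.numeric(substr(ln[1], i, j))
  cell <- c(f(7, 15), f(16, 24), f(25, 33), f(34, 40), f(41, 47), f(48, 54))
  if (any(is.na(cell))) return(numeric(0))
  # placeholder CRYST1 of non-crystallographic entries
  if (all(cell[1:3] == 1)) return(numeric(0))
  cell
}

# operator list lines: "REMARK 290       1555   X,Y,Z"
parseRemark290 <- function(lines) {
  ln <- grep("^REMARK 290\\s+[0-9]+555\\s+\\S", lines, value = TRUE)
  if (!length(ln)) return(list())
  ops <- lapply(ln, function(l) {
    xyz <- trimws(sub("^REMARK 290\\s+[0-9]+555\\s+", "", l))
    parseSymopXyz(xyz)
  })
  ops
}

#' Parse and format fractional symmetry operator strings
#'
#' Converts between the standard crystallographic operator notation
#' (e.g. `"-X,Y+1/2,-Z"`) and a fractional-coordinate rotation/translation
#' pair.
#'
#' @param xyz operator string with three comma-separated terms.
#' @return `parseSymopXyz`: list with 3x3 `R` and length-3 `t`.
#' @export
parseSymopXyz <- function(xyz) {
  terms <- strsplit(toupper(gsub("\\s", "", xyz)), ",")[[1]]
  if (length(terms) != 3L) stop("bad symmetry operator: ", xyz)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    term <- terms[i]
    # tokens: [+-]?X|Y|Z or [+-]?n/m or [+-]?n(.n)?
    toks <- regmatches(term,
      gregexpr("[+-]?([XYZ]|[0-9]+/[0-9]+|[0-9]*\\.?[0-9]+)", term))[[1]]
    if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(term))
      stop("bad symmetry operator term: ", term)
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("X", "Y", "Z")) {
        R[i, match(body, c("X", "Y", "Z"))] <- sgn
      } else if (grepl("/", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        t[i] <- t[i] + sgn * nm[1] / nm[2]
      } else {
        t[i] <- t[i] + sgn * as.numeric(body)
      }
    }
  }
  list(R = R, t = t)
}

#' @describeIn parseSymopXyz format an operator back to string notation.
#' @param op list with `R` and `t` in fractional coordinates.
#' @export
formatSymopXyz <- function(op) {
  axes <- c("X", "Y", "Z")
  terms <- vapply(1:3, function(i) {
    parts <- character(0)
    for (j in 1:3) {
      v <- op$R[i, j]
      if (abs(v) > 1e-9) {
        s <- if (v < 0) "-" else if (length(parts)) "+" else ""
        parts <- c(parts, paste0(s, axes[j]))
      }
    }
    tv <- op$t[i]
    if (abs(tv) > 1e-9) {
      fr <- fracString(tv)
      parts <- c(parts, paste0(if (tv > 0 && length(parts)) "+" else "", fr))
    }
    if (!length(parts)) "0" else paste(parts, collapse = "")
  }, character(1))
  paste(terms, collapse = ",")
}

fracString <- function(v) {
  for (den in c(2, 3, 4, 6)) {
    num <- v * den
    if (abs(num - round(num)) < 1e-9)
      return(paste0(round(num), "/", den))
  }
  format(v)
}

identityOp <- function() list(R = diag(3), t = numeric(3))

# ---- mmCIF header categories ----------------------------------------------

# minimal tokenizer for the few non-atom categories we consume
cifTagValue <- function(lines, tag) {
  ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
  if (!length(ln)) return(NA_character_)
  trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
}

cifCell <- function(lines) {
  tags <- paste0("_cell.", c("length_a", "length_b", "length_c",
                             "angle_alpha", "angle_beta", "angle_gamma"))
  vals <- suppressWarnings(as.numeric(vapply(tags, cifTagValue,
                                             character(1), lines = lines)))
  if (any(is.na(vals))) numeric(0) else vals
}

# read a whole loop_ block containing the given tag prefix; returns a
# data.frame of the loop columns (values whitespace-split, quotes stripped)
cifLoop <- function(lines, prefix) {
  starts <- grep("^loop_\\s*$", lines)
  for (s in starts) {
    i <- s + 1L
    tags <- character(0)
    while (i <= length(lines) && grepl("^_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(startsWith(tags, prefix))) next
    rows <- list()
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (!nzchar(l) || grepl("^(loop_|_|#|data_)", l)) break
      vals <- scan(text = l, what = character(), quiet = TRUE)
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    m <- do.call(rbind, rows)
    if (is.null(m) || ncol(m) != length(tags)) return(NULL)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- tags
    return(df)
  }
  NULL
}

cifSymOps <- function(lines) {
  for (tag in c("_symmetry_equiv.pos_as_xyz",
                "_space_group_symop.operation_xyz")) {
    df <- cifLoop(lines, sub("\\.[^.]*$", "", tag))
    if (!is.null(df) && tag %in% names(df)) {
      xyz <- gsub("^['\"]|['\"]$", "", df[[tag]])
      return(lapply(xyz, parseSymopXyz))
    }
    one <- cifTagValue(lines, tag)
    if (!is.na(one))
      return(list(parseSymopXyz(gsub("^['\"]|['\"]$", "", one))))
  }
  list()
}

cifSeqres <- function(lines) {
  df <- cifLoop(lines, "_pdbx_poly_seq_scheme")
  if (is.null(df)) return(list())
  asym <- df[["_pdbx_poly_seq_scheme.asym_id"]]
  mon <- df[["_pdbx_poly_seq_scheme.mon_id"]]
  if (is.null(asym) || is.null(mon)) return(list())
  split(mon, asym)
}

# ---- writers ---------------------------------------------------------------

#' Write a structure as PDB
#'
#' Emits SEQRES, CRYST1, a REMARK 290 symmetry-operator list and fixed-format
#' ATOM records; round-trips through [readStructure()].
#'
#' @param x a [PepStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(x, path) {
  stopifnot(is(x, "PepStructure"))
  out <- character(0)
  if (length(x@symOps))
    out <- c(out, sprintf("REMARK 290    %3d555   %s",
                          seq_along(x@symOps),
                          vapply(x@symOps, formatSymopXyz, character(1))))
  for (cid in names(x@seqres)) {
    sr <- x@seqres[[cid]]
    chunks <- split(sr, ceiling(seq_along(sr) / 13))
    out <- c(out, vapply(seq_along(chunks), function(k) {
      sprintf("SEQRES %3d %s %4d  %s", k, cid, length(sr),
              paste(sprintf("%-3s", chunks[[k]]), collapse = " "))
    }, character(1)))
  }
  if (length(x@cell))
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      x@cell[1], x@cell[2], x@cell[3], x@cell[4], x@cell[5], x@cell[6]))
  a <- x@atoms
  if (nrow(a)) {
    name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                    sprintf(" %-3s", a$atom))
    out <- c(out, sprintf(
      "ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, ifelse(a$altloc == "", " ", a$altloc),
      a$resname, a$chain, a$resno,
      ifelse(a$inscode == "", " ", a$inscode),
      a$x, a$y, a$z, a$occ, a$bfactor, a$element))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a structure as mmCIF
#'
#' Emits `_cell`, symmetry operator strings, `_pdbx_poly_seq_scheme` and the
#' `atom_site` loop; round-trips through [readStructure()].
#'
#' @inheritParams writeStructurePDB
#' @export
writeStructureCIF <- function(x, path) {
  stopifnot(is(x, "PepStructure"))
  out <- sprintf("data_%s",
                 if (nzchar(x@entryId)) x@entryId else "structure")
  if (length(x@cell)) {
    tags <- paste0("_cell.", c("length_a", "length_b", "length_c",
                               "angle_alpha", "angle_beta", "angle_gamma"))
    out <- c(out, sprintf("%s %.4f", tags, x@cell))
  }
  if (length(x@symOps)) {
    out <- c(out, "loop_", "_symmetry_equiv.id",
             "_symmetry_equiv.pos_as_xyz",
             sprintf("%d '%s'", seq_along(x@symOps),
                     vapply(x@symOps, formatSymopXyz, character(1))))
  }
  if (length(x@seqres)) {
    out <- c(out, "loop_", "_pdbx_poly_seq_scheme.asym_id",
             "_pdbx_poly_seq_scheme.seq_id", "_pdbx_poly_seq_scheme.mon_id")
    for (cid in names(x@seqres)) {
      sr <- x@seqres[[cid]]
      out <- c(out, sprintf("%s %d %s", cid, seq_along(sr), sr))
    }
  }
  a <- x@atoms
  out <- c(out, "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  if (nrow(a)) {
    ent <- as.integer(factor(a$chain, levels = unique(a$chain)))
    out <- c(out, sprintf(
      "ATOM %d %s %s %s %s %s %d %s %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      seq_len(nrow(a)), a$element, a$atom,
      ifelse(a$altloc == "", ".", a$altloc), a$resname, a$chain, ent,
      ifelse(is.na(a$seqidx), ".", as.character(a$seqidx + 1L)),
      ifelse(a$inscode == "", "?", a$inscode),
      a$x, a$y, a$z, a$occ, a$bfactor, a$resno, a$resname, a$chain, a$atom))
  }
  out <- c(out, "#")
  writeLines(out, path)
  invisible(path)
}

# ---- sequences -------------------------------------------------------------

#' Extract and clean a one-letter chain sequence
#'
#' Applies the query-preparation cleaning rules: `UNK` entries are removed,
#' non-standard residues at either terminus (e.g. ACE/NH2 caps) are dropped,
#' and internal non-standard residues are mapped to their parent standard
#' residue when a mapping is known (e.g. MSE to M), otherwise removed with a
#' message.
#'
#' @param x a [PepStructure-class].
#' @param chainId chain identifier.
#' @param source `"seqres"` (expressed construct; default) or `"resolved"`
#'   (residues present in the coordinates).
#' @return one-letter sequence string.
#' @export
extractSequence <- function(x, chainId, source = c("seqres", "resolved")) {
  source <- match.arg(source)
  codes <- if (source == "seqres") chainSeqres(x, chainId)
           else uniqueResidues(chainAtoms(x, chainId))$resname
  if (!length(codes))
    stop("chain ", chainId, " has no ", source, " residues")
  cleanSequence(codes, chainId)
}

cleanSequence <- function(codes, chainId = "?") {
  codes <- codes[codes != "UNK"]
  isStd <- codes %in% names(STANDARD_AA3)
  # terminal non-standard residues are treated as modifications and dropped
  while (length(codes) && !isStd[1]) { codes <- codes[-1]; isStd <- isStd[-1] }
  while (length(codes) && !isStd[length(codes)]) {
    codes <- codes[-length(codes)]; isStd <- isStd[-length(isStd)]
  }
  mapped <- character(0)
  for (code in codes) {
    if (code %in% names(STANDARD_AA3)) {
      mapped <- c(mapped, STANDARD_AA3[[code]])
    } else if (code %in% names(NONSTANDARD_PARENT)) {
      mapped <- c(mapped, STANDARD_AA3[[NONSTANDARD_PARENT[[code]]]])
    } else {
      message("chain ", chainId, ": unmapped non-standard residue ", code,
              " removed")
    }
  }
  if (!length(mapped))
    stop("chain ", chainId, ": sequence empty after cleaning")
  paste(mapped, collapse = "")
}

#' Per-residue model confidence from the B-factor column
#'
#' Predicted models carry pLDDT in the B-factor column. All atoms of a
#' residue are expected to share one value (tolerance 1e-3); otherwise the CA
#' atom's value is used with a warning. Values on the 0-100 scale (any raw
#' value > 1.5) are divided by 100, so the result is always on \[0,1\].
#'
#' @param x a [PepStructure-class].
#' @return named list with one numeric vector per chain, residue order.
#' @export
extractPlddt <- function(x) {
  stopifnot(is(x, "PepStructure"))
  out <- list()
  for (cid in chainIds(x)) {
    a <- chainAtoms(x, cid)
    key <- paste(a$resno, a$inscode)
    vals <- vapply(split(seq_len(nrow(a)), factor(key, unique(key))),
                   function(idx) {
      b <- a$bfactor[idx]
      if (diff(range(b)) > 1e-3) {
        ca <- idx[a$atom[idx] == "CA"]
        if (!length(ca))
          stop("chain ", cid, ": mixed per-atom confidence and no CA atom")
        warning("chain ", cid, ": per-atom confidence differs within a ",
                "residue; using the CA value")
        b <- a$bfactor[ca[1]]
      }
      b[1]
    }, numeric(1))
    if (any(vals > 1.5)) vals <- vals / 100
    if (any(vals < 0) || any(vals > 1))
      stop("chain ", cid, ": confidence values outside [0,100]")
    out[[cid]] <- unname(vals)
  }
  out
}

#' Pair residues of a model chain with a native chain
#'
#' Pairing is by SEQRES index (`seqidx`), the index both chains share because
#' models are built from the cleaned SEQRES sequence. Residues unresolved in
#' either structure are excluded, so the pairing is a partial injection.
#'
#' @param modelAtoms,nativeAtoms atom tables of the two chains.
#' @return data.frame with columns `seqidx`, `model_resno`, `native_resno`,
#'   ordered by `seqidx`.
#' @export
mapResidues <- function(modelAtoms, nativeAtoms) {
  rm_ <- uniqueResidues(modelAtoms); rn <- uniqueResidues(nativeAtoms)
  rm_ <- rm_[!is.na(rm_$seqidx), ]; rn <- rn[!is.na(rn$seqidx), ]
  shared <- intersect(rm_$seqidx, rn$seqidx)
  if (!length(shared))
    stop("no residues in common between model and native chain")
  shared <- sort(shared)
  data.frame(seqidx = shared,
             model_resno = rm_$resno[match(shared, rm_$seqidx)],
             native_resno = rn$resno[match(shared, rn$seqidx)])
}

# ---- FASTA -----------------------------------------------------------------

#' Write sequences to FASTA
#'
#' @param records named character vector (names become headers) or list of
#'   `(id, sequence)` pairs.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.list(records))
    records <- stats::setNames(
      vapply(records, function(r) r[[2]], character(1)),
      vapply(records, function(r) r[[1]], character(1)))
  if (!length(records)) stop("no records to write")
  if (any(!nzchar(records)) || any(grepl("[^A-Za-z]", records)))
    stop("sequences must be non-empty and alphabetic")
  seqs <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @describeIn writeFasta read FASTA back as a named character vector.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}
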