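# Complex-quality metrics: interface definition, FlexPepDock-style RMSDs,
# CAPRI Irms/Lrms/Fnat, DockQ, per-residue RMSD, binding pocket operators,
# per-chain RMSD.
#
# Atom pairing between model and native is always by (seqidx, atom name) on
# heavy atoms; atoms missing on either side are dropped from both sides
# symmetrically (e.g. OXT absent from models). Interface residue sets are
# always derived from the native complex, never from the model.

# paired coordinate matrices for atoms shared by two chains
pairedCoords <- function(aAtoms, bAtoms, residues = NULL,
                         backboneOnly = FALSE) {
  a <- heavyAtoms(aAtoms); b <- heavyAtoms(bAtoms)
  if (!is.null(residues)) {
    a <- a[a$seqidx %in% residues, , drop = FALSE]
    b <- b[b$seqidx %in% residues, , drop = FALSE]
  }
  if (backboneOnly) {
    a <- a[a$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    b <- b[b$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  }
  keyA <- paste(a$seqidx, a$atom); keyB <- paste(b$seqidx, b$atom)
  shared <- intersect(keyA, keyB)
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  ca <- atomCoords(a)[ia, , drop = FALSE]
  cb <- atomCoords(b)[ib, , drop = FALSE]
  rownames(ca) <- rownames(cb) <- shared
  list(a = ca, b = cb, keys = shared)
}

# representative interface atom per residue: CB, or CA for glycine (and any
# residue lacking CB)
ifAtomCoords <- function(atoms) {
  a <- heavyAtoms(atoms)
  res <- uniqueResidues(a)
  coords <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    sel <- a$resno == res$resno[i] & a$inscode == res$inscode[i]
    cb <- which(sel & a$atom == "CB")
    ca <- which(sel & a$atom == "CA")
    j <- if (length(cb)) cb[1] else if (length(ca)) ca[1] else which(sel)[1]
    coords[i, ] <- c(a$x[j], a$y[j], a$z[j])
  }
  list(seqidx = res$seqidx, coords = coords)
}

#' Define the native interface under the C-beta 8 Angstrom rule
#'
#' A residue on either side belongs to the interface iff its C-beta atom
#' (C-alpha for glycine) lies within `cutoff` of any cross-chain
#' C-beta/C-alpha. Computed on the native complex only.
#'
#' @param native a [SplitComplex-class] (the native).
#' @param cutoff distance cutoff in Angstrom (default 8.0).
#' @return an [InterfaceDefinition-class]; empty sides give a warning and
#'   downstream interface metrics are undefined (`NA`).
#' @export
defineInterface <- function(native, cutoff = 8.0) {
  stopifnot(is(native, "SplitComplex"))
  rec <- ifAtomCoords(native@receptor); pep <- ifAtomCoords(native@peptide)
  d2 <- crossDist2(rec$coords, pep$coords)
  hit <- d2 <= cutoff^2
  recIf <- rec$seqidx[rowSums(hit) > 0]
  pepIf <- pep$seqidx[colSums(hit) > 0]
  if (!length(recIf) || !length(pepIf))
    warning("empty interface at cutoff ", cutoff, " A")
  new("InterfaceDefinition", peptideIf = as.integer(sort(pepIf)),
      receptorIf = as.integer(sort(recIf)), cutoff = cutoff)
}

# superpose model receptor onto native receptor over backbone atoms of all
# mapped receptor residues; returns the transform
receptorSuperpose <- function(native, model) {
  pc <- pairedCoords(native@receptor, model@receptor, backboneOnly = TRUE)
  if (length(pc$keys) < 3L)
    stop("fewer than 3 shared receptor backbone atoms; cannot superpose")
  kabschSuperpose(pc$a, pc$b)
}

transformSplit <- function(split, transform) {
  for (slot in c("receptor", "peptide")) {
    a <- slot(split, slot)
    xyz <- applyTransform(transform, atomCoords(a))
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    slot(split, slot) <- a
  }
  split
}

#' FlexPepDock-style interface RMSDs
#'
#' After superposing the model receptor onto the native receptor (backbone
#' atoms of all shared receptor residues), computes unfitted RMSDs over the
#' peptide interface residues (`rmsBB_if` backbone, `rmsALL_if` heavy atoms)
#' and over the interface residues of both chains (`rmsBB_allIF`,
#' `rmsALL_allIF`).
#'
#' @param native,model [SplitComplex-class] objects in any frame.
#' @param interface the native [InterfaceDefinition-class].
#' @return named numeric: `rmsBB_if`, `rmsALL_if`, `rmsBB_allIF`,
#'   `rmsALL_allIF` (Angstrom; `NA` for sides with an empty interface).
#' @export
fpdRmsdSuite <- function(native, model, interface) {
  stopifnot(is(interface, "InterfaceDefinition"))
  fit <- receptorSuperpose(native, model)
  model <- transformSplit(model, fit)
  pepIf <- interface@peptideIf; recIf <- interface@receptorIf
  pepRms <- function(backbone) {
    if (!length(pepIf)) return(NA_real_)
    pc <- pairedCoords(native@peptide, model@peptide, residues = pepIf,
                       backboneOnly = backbone)
    if (!length(pc$keys)) return(NA_real_)
    coordRmsd(pc$a, pc$b)
  }
  allRms <- function(backbone) {
    if (!length(pepIf) && !length(recIf)) return(NA_real_)
    pp <- pairedCoords(native@peptide, model@peptide, residues = pepIf,
                       backboneOnly = backbone)
    rr <- pairedCoords(native@receptor, model@receptor, residues = recIf,
                       backboneOnly = backbone)
    a <- rbind(pp$a, rr$a); b <- rbind(pp$b, rr$b)
    if (!nrow(a)) return(NA_real_)
    coordRmsd(a, b, .checkLabels = FALSE)
  }
  c(rmsBB_if = pepRms(TRUE), rmsALL_if = pepRms(FALSE),
    rmsBB_allIF = allRms(TRUE), rmsALL_allIF = allRms(FALSE))
}

# residue-level cross-chain contact keys at a heavy-atom cutoff
contactKeys <- function(split, cutoff = 5.0) {
  rec <- heavyAtoms(split@receptor); pep <- heavyAtoms(split@peptide)
  d2 <- crossDist2(atomCoords(rec), atomCoords(pep))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  unique(paste(rec$seqidx[hit[, 1]], pep$seqidx[hit[, 2]], sep = "|"))
}

#' CAPRI complex-quality metrics
#'
#' `Irms` is the backbone RMSD over the interface residues of both chains
#' after superposing on exactly those atoms; `Lrms` is the backbone RMSD over
#' all peptide (ligand) residues after superposing on the receptor backbone;
#' `Fnat` is the fraction of native cross-chain residue-residue contacts (any
#' heavy-atom pair within 5.0 Angstrom) that are present in the model.
#'
#' @inheritParams fpdRmsdSuite
#' @param fnatCutoff heavy-atom contact cutoff for Fnat (default 5.0).
#' @return named numeric: `Irms`, `Lrms`, `Fnat`.
#' @export
capriMetrics <- function(native, model, interface, fnatCutoff = 5.0) {
  stopifnot(is(interface, "InterfaceDefinition"))
  pepIf <- interface@peptideIf; recIf <- interface@receptorIf
  Irms <- NA_real_
  if (length(pepIf) || length(recIf)) {
    pp <- pairedCoords(native@peptide, model@peptide, residues = pepIf,
                       backboneOnly = TRUE)
    rr <- pairedCoords(native@receptor, model@receptor, residues = recIf,
                       backboneOnly = TRUE)
    a <- rbind(pp$a, rr$a); b <- rbind(pp$b, rr$b)
    if (nrow(a) >= 3L) Irms <- kabschSuperpose(a, b)$rmsd
  }
  fit <- receptorSuperpose(native, model)
  moved <- transformSplit(model, fit)
  lp <- pairedCoords(native@peptide, moved@peptide, backboneOnly = TRUE)
  Lrms <- if (length(lp$keys)) coordRmsd(lp$a, lp$b) else NA_real_
  natContacts <- contactKeys(native, fnatCutoff)
  Fnat <- if (!length(natContacts)) {
    warning("native complex has no cross-chain contacts at ", fnatCutoff,
            " A; Fnat undefined")
    NA_real_
  } else {
    modContacts <- contactKeys(moved, fnatCutoff)
    length(intersect(natContacts, modContacts)) / length(natContacts)
  }
  c(Irms = Irms, Lrms = Lrms, Fnat = Fnat)
}

#' DockQ composite quality score
#'
#' `DockQ = (Fnat + 1/(1+(Irms/d1)^2) + 1/(1+(Lrms/d2)^2)) / 3` with the
#' default constants `d1 = 1.5` and `d2 = 8.5` Angstrom. A perfect model
#' (`Fnat = 1`, both RMSDs 0) scores 1; as both RMSDs grow the score tends to
#' `Fnat / 3`.
#'
#' @param Fnat fraction of native contacts reproduced, in \[0,1\].
#' @param Lrms ligand (peptide backbone) RMSD, Angstrom.
#' @param Irms interface backbone RMSD, Angstrom.
#' @param d1,d2 scaling constants (defaults 1.5 and 8.5).
#' @return DockQ score in \[0,1\].
#' @examples
#' dockqScore(1, 0, 0)        # 1
#' dockqScore(0, 8.5, 1.5)    # 1/3
#' @export
dockqScore <- function(Fnat, Lrms, Irms, d1 = 1.5, d2 = 8.5) {
  if (any(Fnat < 0 | Fnat > 1, na.rm = TRUE))
    stop("Fnat must lie in [0,1]")
  if (any(c(Lrms, Irms) < 0, na.rm = TRUE))
    stop("RMSD arguments must be non-negative")
  (Fnat + 1 / (1 + (Irms / d1)^2) + 1 / (1 + (Lrms / d2)^2)) / 3
}

#' Per-residue peptide RMSD
#'
#' After the receptor superposition of [fpdRmsdSuite()], computes for every
#' peptide residue the heavy-atom RMSD over atoms present in both structures
#' (atoms lacking in the model, such as OXT, are ignored). Residues
#' unresolved in the native are reported as skipped.
#'
#' @inheritParams fpdRmsdSuite
#' @return data.frame with columns `seqidx` (0-based peptide index), `rmsd`
#'   (Angstrom, `NA` when skipped), `skipped` (logical), `n_atoms`.
#' @export
perResidueRmsd <- function(native, model) {
  fit <- receptorSuperpose(native, model)
  model <- transformSplit(model, fit)
  modRes <- uniqueResidues(model@peptide)
  natRes <- uniqueResidues(native@peptide)
  idx <- sort(unique(modRes$seqidx))
  out <- lapply(idx, function(i) {
    if (!i %in% natRes$seqidx)
      return(data.frame(seqidx = i, rmsd = NA_real_, skipped = TRUE,
                        n_atoms = 0L))
    pc <- pairedCoords(native@peptide, model@peptide, residues = i)
    if (!length(pc$keys))
      return(data.frame(seqidx = i, rmsd = NA_real_, skipped = TRUE,
                        n_atoms = 0L))
    data.frame(seqidx = i, rmsd = coordRmsd(pc$a, pc$b), skipped = FALSE,
               n_atoms = length(pc$keys))
  })
  do.call(rbind, out)
}

#' Receptor binding-pocket residues
#'
#' Receptor residues with at least one backbone atom within `cutoff` of any
#' peptide backbone atom.
#'
#' @param split a [SplitComplex-class].
#' @param cutoff distance cutoff in Angstrom (default 8.0).
#' @return integer vector of receptor `seqidx` values (sorted).
#' @export
pocketResidues <- function(split, cutoff = 8.0) {
  stopifnot(is(split, "SplitComplex"))
  rec <- split@receptor[split@receptor$atom %in% BACKBONE_ATOMS, ,
                        drop = FALSE]
  pep <- split@peptide[split@peptide$atom %in% BACKBONE_ATOMS, ,
                       drop = FALSE]
  if (!nrow(rec) || !nrow(pep)) return(integer(0))
  d2 <- crossDist2(atomCoords(rec), atomCoords(pep))
  hit <- rowSums(d2 <= cutoff^2) > 0
  sort(unique(rec$seqidx[hit]))
}

#' Fraction of the native binding pocket recovered by a model
#'
#' @param native,model [SplitComplex-class] objects; pockets are computed on
#'   each and intersected by receptor `seqidx`.
#' @param cutoff pocket cutoff in Angstrom (default 8.0).
#' @return fraction in \[0,1\].
#' @export
pocketRecovery <- function(native, model, cutoff = 8.0) {
  nat <- pocketResidues(native, cutoff)
  if (!length(nat)) stop("native pocket is empty")
  mod <- pocketResidues(model, cutoff)
  length(intersect(nat, mod)) / length(nat)
}

#' Fitted RMSD of an individual chain
#'
#' Superposes the model chain onto the native chain over all shared heavy
#' atoms in a single pass, with no outlier rejection cycles, and returns the
#' fitted RMSD.
#'
#' @param nativeAtoms,modelAtoms atom tables of the two chains.
#' @return RMSD in Angstrom.
#' @export
chainRmsd <- function(nativeAtoms, modelAtoms) {
  pc <- pairedCoords(nativeAtoms, modelAtoms)
  if (length(pc$keys) < 3L) stop("fewer than 3 shared atoms")
  kabschSuperpose(pc$a, pc$b)$rmsd
}

#' Occupancy of the native peptide pocket by a candidate chain
#'
#' For screening monomer structures that may already contain a
#' peptide-like element in the binding site: the fraction of native pocket
#' residues having at least one backbone atom within `cutoff` of any
#' candidate-chain backbone atom. The candidate must already be superposed
#' into the native receptor frame by the caller.
#'
#' @param native the native [SplitComplex-class].
#' @param candidateAtoms atom table of the candidate chain (native frame).
#' @param cutoff distance cutoff in Angstrom (default 8.0).
#' @return fraction in \[0,1\].
#' @export
pocketOccupancy <- function(native, candidateAtoms, cutoff = 8.0) {
  pocket <- pocketResidues(native, cutoff)
  if (!length(pocket)) stop("native pocket is empty")
  rec <- native@receptor[native@receptor$atom %in% BACKBONE_ATOMS &
                           native@receptor$seqidx %in% pocket, ,
                         drop = FALSE]
  cand <- candidateAtoms[candidateAtoms$atom %in% BACKBONE_ATOMS, ,
                         drop = FALSE]
  if (!nrow(cand)) stop("candidate chain has no backbone atoms")
  d2 <- crossDist2(atomCoords(rec), atomCoords(cand))
  hit <- rowSums(d2 <= cutoff^2) > 0
  length(unique(rec$seqidx[hit])) / length(pocket)
}

#' Evaluate one model against its native complex
#'
#' Runs the full metric suite: interface definition on the native,
#' FlexPepDock-style interface RMSDs, CAPRI metrics, DockQ, per-chain RMSDs,
#' pocket recovery and the failure flag.
#'
#' @param native,model [SplitComplex-class] objects.
#' @param interfaceCutoff interface rule cutoff (default 8.0).
#' @param contactCutoff failure-detection cutoff (default 4.0).
#' @param fnatCutoff Fnat contact cutoff (default 5.0).
#' @return one-row data.frame with columns `rmsBB_if`, `rmsALL_if`,
#'   `rmsBB_allIF`, `rmsALL_allIF`, `Irms`, `Lrms`, `Fnat`, `DockQ`,
#'   `receptor_rmsd`, `peptide_rmsd`, `pocket_recovery`, `failed`.
#' @export
evaluateComplex <- function(native, model, interfaceCutoff = 8.0,
                            contactCutoff = 4.0, fnatCutoff = 5.0) {
  interface <- defineInterface(native, interfaceCutoff)
  fpd <- fpdRmsdSuite(native, model, interface)
  capri <- capriMetrics(native, model, interface, fnatCutoff)
  dq <- dockqScore(capri[["Fnat"]], capri[["Lrms"]], capri[["Irms"]])
  data.frame(rmsBB_if = fpd[["rmsBB_if"]], rmsALL_if = fpd[["rmsALL_if"]],
             rmsBB_allIF = fpd[["rmsBB_allIF"]],
             rmsALL_allIF = fpd[["rmsALL_allIF"]],
             Irms = capri[["Irms"]], Lrms = capri[["Lrms"]],
             Fnat = capri[["Fnat"]], DockQ = dq,
             receptor_rmsd = chainRmsd(native@receptor, model@receptor),
             peptide_rmsd = chainRmsd(native@peptide, model@peptide),
             pocket_recovery = pocketRecovery(native, model,
                                             interfaceCutoff),
             failed = detectFailure(model, contactCutoff))
}
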