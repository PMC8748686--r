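# Synthetic-data generator: toy receptor-peptide complexes with analytically
# known geometry, perturbation operators with known RMSD effects, synthetic
# crystals, confidence and ddG tables, and the deterministic mock predictor.
#
# Fixtures are pure functions of (spec, seed). Each generator records its
# ground truth (interface sets, contact fractions, per-residue displacement)
# in a "groundTruth" attribute computed with plain double loops, independent
# of the vectorised metric implementations it is used to test.

# ideal alpha-helix backbone: rise 1.5 A per residue, 100 degree twist,
# CA radius 2.3 A; N/C placed on the helical curve at +/- 0.35 residue,
# O and CB on radial offsets. Self-consistent rather than physical.
helixPoint <- function(tt, origin, phase = 0) {
  ang <- phase + tt * 100 * pi / 180
  origin + c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * tt)
}

radialOut <- function(p, origin) {
  v <- c(p[1] - origin[1], p[2] - origin[2], 0)
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0, 0) else v / n
}

helixResidueAtoms <- function(i, origin, phase = 0) {
  ca <- helixPoint(i, origin, phase)
  n <- helixPoint(i - 0.35, origin, phase)
  cc <- helixPoint(i + 0.35, origin, phase)
  o <- cc + radialOut(cc, origin) * 1.23
  cb <- ca + radialOut(ca, origin) * 1.53 + c(0, 0, 0.4)
  rbind(N = n, CA = ca, C = cc, O = o, CB = cb)
}

extendedResidueAtoms <- function(j, start) {
  ca <- start + c(0, 0, 3.5 * j)
  n <- ca + c(0.35, 0.45, -1.2)
  cc <- ca + c(-0.35, -0.45, 1.2)
  o <- cc + c(0, 1.23, 0)
  cb <- ca + c(-1.45, 0, 0.4)   # points toward the receptor (at lower x)
  rbind(N = n, CA = ca, C = cc, O = o, CB = cb)
}

residueRows <- function(atomMat, chain, resno, resname, bfactor = 60) {
  data.frame(chain = chain, resno = as.integer(resno), inscode = "",
             resname = resname, seqidx = as.integer(resno - 1L),
             atom = rownames(atomMat), element = substr(rownames(atomMat),
                                                        1, 1),
             x = atomMat[, 1], y = atomMat[, 2], z = atomMat[, 3],
             occ = 1, bfactor = bfactor, altloc = "",
             stringsAsFactors = FALSE)
}

randomSeq3 <- function(n) {
  # three-letter codes, glycine excluded so every residue carries a CB
  sample(setdiff(names(STANDARD_AA3), "GLY"), n, replace = TRUE)
}

#' Generate a toy receptor-peptide complex with known geometry
#'
#' The receptor is built as a bundle of ideal alpha-helices (up to 30
#' residues each, parallel, 11 Angstrom apart) with full backbone plus
#' C-beta; the peptide is placed alongside the first helix at `grooveOffset`
#' Angstrom from the receptor surface, as an extended strand or a short
#' helix. The construction is deterministic given `seed`; the brute-force
#' interface and pocket residue sets are recorded in the `groundTruth`
#' attribute.
#'
#' @param receptorLen receptor length in residues (default 40).
#' @param peptideLen peptide length in residues (default 8).
#' @param peptideGeometry `"extended"` or `"helix"`.
#' @param grooveOffset distance from the receptor surface to the peptide
#'   C-alpha line, Angstrom (default 4.0; large values give an empty
#'   interface).
#' @param seed integer seed (sequences only; geometry is deterministic).
#' @return a [SplitComplex-class] native with chains A (receptor) and B
#'   (peptide); `attr(, "groundTruth")` holds `interface` (list of peptide /
#'   receptor seqidx sets at 8 A), `pocket` (receptor seqidx set at 8 A) and
#'   the construction parameters.
#' @export
makeToyComplex <- function(receptorLen = 40L, peptideLen = 8L,
                           peptideGeometry = c("extended", "helix"),
                           grooveOffset = 4.0, seed = 1L) {
  peptideGeometry <- match.arg(peptideGeometry)
  receptorLen <- as.integer(receptorLen); peptideLen <- as.integer(peptideLen)
  if (receptorLen < 2L || peptideLen < 1L) stop("infeasible fixture size")
  withSeed(seed, {
    recSeq <- randomSeq3(receptorLen)
    pepSeq <- randomSeq3(peptideLen)
  })
  # receptor helix bundle
  rows <- list()
  segLen <- 30L
  for (i in seq_len(receptorLen)) {
    seg <- (i - 1L) %/% segLen
    within <- (i - 1L) %% segLen
    origin <- c(-11 * seg, 0, 0)
    rows[[i]] <- residueRows(helixResidueAtoms(within, origin), "A", i,
                             recSeq[i])
  }
  rec <- do.call(rbind, rows)
  # peptide along the first helix, centred on its z-extent
  surfX <- max(rec$x[rec$chain == "A" & rec$resno <= segLen])
  zmid <- mean(range(rec$z[rec$resno <= min(receptorLen, segLen)]))
  startZ <- zmid - 3.5 * (peptideLen - 1) / 2
  pepStart <- c(surfX + grooveOffset, 0, startZ)
  rows <- lapply(seq_len(peptideLen), function(j) {
    m <- if (peptideGeometry == "extended")
      extendedResidueAtoms(j - 1L, pepStart)
    else
      helixResidueAtoms(j - 1L, pepStart + c(2.3, 0, 0), phase = pi)
    residueRows(m, "B", j, pepSeq[j])
  })
  pep <- do.call(rbind, rows)
  rownames(rec) <- rownames(pep) <- NULL
  native <- SplitComplex(rec, pep, receptorSeqres = recSeq,
                         peptideSeqres = pepSeq, linkerDiscarded = 0L)
  truth <- list(
    interface = bruteInterface(rec, pep, 8.0),
    pocket = brutePocket(rec, pep, 8.0),
    receptorLen = receptorLen, peptideLen = peptideLen,
    peptideGeometry = peptideGeometry, grooveOffset = grooveOffset,
    seed = seed)
  attr(native, "groundTruth") <- truth
  native
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# plain double-loop interface computation (generator-side ground truth)
bruteInterface <- function(rec, pep, cutoff) {
  recRes <- split(seq_len(nrow(rec)), rec$resno)
  pepRes <- split(seq_len(nrow(pep)), pep$resno)
  ifAtom <- function(df, idx) {
    cb <- idx[df$atom[idx] == "CB"]
    j <- if (length(cb)) cb[1] else idx[df$atom[idx] == "CA"][1]
    c(df$x[j], df$y[j], df$z[j])
  }
  recIf <- integer(0); pepIf <- integer(0)
  for (rn in names(recRes)) for (pn in names(pepRes)) {
    d <- sqrt(sum((ifAtom(rec, recRes[[rn]]) -
                     ifAtom(pep, pepRes[[pn]]))^2))
    if (d <= cutoff) {
      recIf <- c(recIf, rec$seqidx[recRes[[rn]][1]])
      pepIf <- c(pepIf, pep$seqidx[pepRes[[pn]][1]])
    }
  }
  list(peptideIf = sort(unique(pepIf)), receptorIf = sort(unique(recIf)))
}

brutePocket <- function(rec, pep, cutoff) {
  recB <- rec[rec$atom %in% BACKBONE_ATOMS, ]
  pepB <- pep[pep$atom %in% BACKBONE_ATOMS, ]
  hits <- integer(0)
  for (i in seq_len(nrow(recB))) {
    for (j in seq_len(nrow(pepB))) {
      d <- sqrt((recB$x[i] - pepB$x[j])^2 + (recB$y[i] - pepB$y[j])^2 +
                  (recB$z[i] - pepB$z[j])^2)
      if (d <= cutoff) { hits <- c(hits, recB$seqidx[i]); break }
    }
  }
  sort(unique(hits))
}

rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Perturb a native complex into a model of known quality
#'
#' The receptor is copied exactly; the peptide is rigidly rotated about its
#' centroid, translated, and optionally jittered with isotropic Gaussian
#' noise. With zero rotation and noise, the peptide RMSD after receptor
#' alignment is exactly the norm of the shift. The per-residue C-alpha
#' displacement is recorded in the `groundTruth` attribute.
#'
#' @param native a [SplitComplex-class].
#' @param peptideShift length-3 translation, Angstrom.
#' @param peptideRot rotation angle about a seeded random axis through the
#'   peptide centroid, degrees.
#' @param noiseSigma isotropic Gaussian noise sd per coordinate, Angstrom.
#' @param seed integer seed (rotation axis and noise).
#' @return a [SplitComplex-class] model.
#' @export
perturbModel <- function(native, peptideShift = c(0, 0, 0), peptideRot = 0,
                         noiseSigma = 0, seed = 1L) {
  stopifnot(is(native, "SplitComplex"))
  pep <- native@peptide
  xyz <- atomCoords(pep)
  withSeed(seed, {
    if (peptideRot != 0) {
      axis <- stats::rnorm(3)
      ctr <- colMeans(xyz)
      R <- rotationMatrix(axis, peptideRot)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
    }
    xyz <- sweep(xyz, 2, as.numeric(peptideShift), "+")
    if (noiseSigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noiseSigma),
                          nrow(xyz), 3)
  })
  pep$x <- xyz[, 1]; pep$y <- xyz[, 2]; pep$z <- xyz[, 3]
  model <- SplitComplex(native@receptor, pep,
                        receptorSeqres = native@receptorSeqres,
                        peptideSeqres = native@peptideSeqres,
                        linkerDiscarded = 0L)
  natCa <- native@peptide[native@peptide$atom == "CA", ]
  modCa <- pep[pep$atom == "CA", ]
  disp <- sqrt((natCa$x - modCa$x)^2 + (natCa$y - modCa$y)^2 +
                 (natCa$z - modCa$z)^2)
  attr(model, "groundTruth") <- list(shift = peptideShift,
                                     rot = peptideRot,
                                     noiseSigma = noiseSigma,
                                     caDisplacement = disp)
  model
}

#' Model with the peptide thrown out into space
#'
#' Translates the peptide 50 Angstrom along the receptor-to-peptide axis,
#' reproducing the characteristic failure mode in which the peptide does not
#' interact with the receptor.
#'
#' @param native a [SplitComplex-class].
#' @param distance translation distance, Angstrom (default 50).
#' @return a [SplitComplex-class] model; [detectFailure()] is TRUE on it.
#' @export
makeThrownModel <- function(native, distance = 50) {
  stopifnot(is(native, "SplitComplex"))
  axis <- colMeans(atomCoords(native@peptide)) -
    colMeans(atomCoords(native@receptor))
  axis <- axis / sqrt(sum(axis^2))
  perturbModel(native, peptideShift = axis * distance, seed = 0L)
}

#' Build a synthetic crystal with a chosen symmetry-contact fraction
#'
#' Embeds the native complex in a P1 cell (identity operator only) whose
#' a-axis length is chosen so the +a lattice translation places a symmetry
#' mate in 4-Angstrom contact with exactly
#' `ceiling(targetContactFraction * peptideLen)` peptide residues; the b and
#' c axes are padded far beyond contact range. The realised fraction is
#' verified by brute force and recorded in the `groundTruth` attribute.
#'
#' @param native a [SplitComplex-class].
#' @param targetContactFraction desired fraction of peptide residues in
#'   symmetry-mate contact, in \[0,1\].
#' @param contactCutoff contact cutoff, Angstrom (default 4.0).
#' @return a [PepStructure-class] with chains A/B, cell and identity
#'   operator; `attr(, "groundTruth")$fraction` holds the realised fraction.
#' @export
makeCrystalFixture <- function(native, targetContactFraction,
                               contactCutoff = 4.0) {
  stopifnot(is(native, "SplitComplex"))
  if (targetContactFraction < 0 || targetContactFraction > 1)
    stop("targetContactFraction must lie in [0,1]")
  au <- rbind(native@receptor, native@peptide)
  pep <- native@peptide
  nPep <- nrow(uniqueResidues(pep))
  k <- ceiling(targetContactFraction * nPep)
  # Along a chosen cell axis m, peptide residue r contacts the +m mate iff
  # the axis length falls inside one of its pair intervals
  # [p_m - q_m - s, p_m - q_m + s], s = sqrt(cutoff^2 - d_perp^2), over atom
  # pairs (p in r, q in the asymmetric unit). Enumerate the intervals and
  # pick the largest length realising exactly k contacting residues while
  # the -m mate stays out of range; axes are tried in turn since threshold
  # spacing depends on the geometry along each.
  pepRes <- split(seq_len(nrow(pep)), pep$resno)
  auXyz <- cbind(au$x, au$y, au$z)
  pepXyz <- cbind(pep$x, pep$y, pep$z)
  pad <- 2 * contactCutoff + 20
  axisIntervals <- function(m) {
    perp <- setdiff(1:3, m)
    lapply(pepRes, function(idx) {
      lo <- numeric(0); hi <- numeric(0)
      for (i in idx) for (j in seq_len(nrow(au))) {
        dp2 <- (pepXyz[i, perp[1]] - auXyz[j, perp[1]])^2 +
          (pepXyz[i, perp[2]] - auXyz[j, perp[2]])^2
        if (dp2 <= contactCutoff^2) {
          s <- sqrt(contactCutoff^2 - dp2)
          lo <- c(lo, pepXyz[i, m] - auXyz[j, m] - s)
          hi <- c(hi, pepXyz[i, m] - auXyz[j, m] + s)
        }
      }
      cbind(lo = lo, hi = hi)
    })
  }
  axis <- NA_integer_; aLen <- NA_real_
  if (k == 0L) {
    axis <- 1L
    iv <- axisIntervals(1L)
    ends <- unlist(lapply(iv, as.numeric))
    aLen <- max(c(ends, diff(range(au$x)), 0)) + pad
  } else {
    for (m in c(1L, 3L, 2L)) {
      iv <- axisIntervals(m)
      countAt <- function(a) sum(vapply(iv, function(r)
        nrow(r) > 0 && any(a >= r[, "lo"] & a <= r[, "hi"]), logical(1)))
      minA <- max(auXyz[, m]) - min(pepXyz[, m]) + contactCutoff + 0.5
      ends <- unlist(lapply(iv, as.numeric))
      events <- sort(unique(c(ends[ends > minA], minA)))
      if (length(events) < 2L) next
      mids <- (utils::head(events, -1) + utils::tail(events, -1)) / 2
      cand <- rev(mids[diff(events) > 0.02])
      for (a in cand) if (countAt(a) == k) { axis <- m; aLen <- a; break }
      if (!is.na(aLen)) break
    }
    if (is.na(aLen))
      stop("infeasible target fraction for this geometry")
  }
  extents <- c(diff(range(au$x)), diff(range(au$y)), diff(range(au$z)))
  cell <- c(extents + pad, 90, 90, 90)
  cell[axis] <- aLen
  st <- splitToStructure(native, entryId = "crystal-fixture", cell = cell,
                         symOps = list(identityOp()))
  # brute-force verification over all 26 neighbour translations
  contacts <- logical(nPep)
  resIds <- as.integer(names(pepRes))
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    shift <- c(sx * cell[1], sy * cell[2], sz * cell[3])
    for (r in seq_along(pepRes)) {
      if (contacts[r]) next
      idx <- pepRes[[r]]
      for (i in idx) {
        d2 <- (pep$x[i] - (au$x + shift[1]))^2 +
          (pep$y[i] - (au$y + shift[2]))^2 +
          (pep$z[i] - (au$z + shift[3]))^2
        if (any(d2 <= contactCutoff^2)) { contacts[r] <- TRUE; break }
      }
    }
  }
  fraction <- sum(contacts) / nPep
  if (k > 0 && abs(fraction - k / nPep) > 1e-12)
    stop("crystal construction failed to realise the target fraction")
  attr(st, "groundTruth") <- list(fraction = fraction,
                                  contactResidues = resIds[contacts],
                                  target = targetContactFraction)
  st
}

#' Synthetic per-residue confidence from known displacements
#'
#' Maps each per-residue displacement to a confidence value through the
#' monotone-decreasing rule `0.7 ^ (d / 2.5)` -- calibrated so a residue
#' displaced exactly 2.5 Angstrom sits exactly at the 0.7 confidence mark --
#' plus bounded uniform noise, clamped to \[0,1\].
#'
#' @param displacement per-residue displacements, Angstrom.
#' @param noise half-width of the uniform noise (default 0).
#' @param seed integer seed.
#' @return numeric vector of confidence values in \[0,1\].
#' @export
synthConfidence <- function(displacement, noise = 0, seed = 1L) {
  base <- 0.7^(displacement / 2.5)
  withSeed(seed, {
    if (noise > 0)
      base <- base + stats::runif(length(base), -noise, noise)
  })
  pmin(1, pmax(0, base))
}

#' Synthetic paired alanine-scanning ddG tables
#'
#' Draws a native ddG table with a known hotspot fraction around the
#' 1.5 kcal/mol hotspot line (hotspots uniform on \[1.7, 4.0\], others on
#' \[-1.0, 1.3\]) and a model table equal to the native values plus Gaussian
#' noise.
#'
#' @param n number of residues.
#' @param hotspotFraction fraction of native hotspots, in \[0,1\].
#' @param noiseSigma model-noise sd, kcal/mol.
#' @param seed integer seed.
#' @return list with data.frames `native` and `model` (columns `residue`,
#'   `ddG`) and the logical ground-truth vector `isHotspot`.
#' @export
synthAlascan <- function(n, hotspotFraction = 0.3, noiseSigma = 0.5,
                         seed = 1L) {
  if (hotspotFraction < 0 || hotspotFraction > 1)
    stop("hotspotFraction must lie in [0,1]")
  nHot <- round(hotspotFraction * n)
  withSeed(seed, {
    isHot <- sample(rep(c(TRUE, FALSE), c(nHot, n - nHot)))
    nat <- ifelse(isHot, stats::runif(n, 1.7, 4.0),
                  stats::runif(n, -1.0, 1.3))
    mod <- nat + stats::rnorm(n, 0, noiseSigma)
  })
  list(native = data.frame(residue = seq_len(n), ddG = nat),
       model = data.frame(residue = seq_len(n), ddG = mod),
       isHotspot = isHot)
}

#' Deterministic mock predictor
#'
#' Implements the predictor contract on fixture data: returns the fixture
#' native transformed according to `behavior`, re-fused through a 30-residue
#' glycine linker arc for linked-mode queries, with confidence values derived
#' from the known per-residue displacement via [synthConfidence()] and
#' carried in the B-factor column on the 0-100 scale. Deterministic given
#' `(query, native, behavior, seed)`.
#'
#' @param query a [DockingQuery-class] built from the fixture (see
#'   [fixtureQuery()]).
#' @param native the fixture [SplitComplex-class].
#' @param behavior `"perfect"`, `"shifted"` (3 Angstrom peptide shift),
#'   `"thrown"` (50 Angstrom), or `"noisy"` (0.5 Angstrom jitter).
#' @param seed integer seed.
#' @return a [PredictedModel-class].
#' @export
mockPredictor <- function(query, native,
                          behavior = c("perfect", "shifted", "thrown",
                                       "noisy"),
                          seed = 1L) {
  behavior <- match.arg(behavior)
  stopifnot(is(query, "DockingQuery"), is(native, "SplitComplex"))
  model <- switch(behavior,
    perfect = perturbModel(native, seed = seed),
    shifted = perturbModel(native, peptideShift = c(3, 0, 0), seed = seed),
    thrown = makeThrownModel(native),
    noisy = perturbModel(native, noiseSigma = 0.5, seed = seed))
  disp <- attr(model, "groundTruth")$caDisplacement
  pepPlddt <- synthConfidence(disp, noise = 0.02, seed = seed + 1L)
  recPlddt <- rep(0.95, nrow(uniqueResidues(model@receptor)))
  rec <- model@receptor; pep <- model@peptide
  R <- nrow(uniqueResidues(rec)); P <- nrow(uniqueResidues(pep))
  rec$bfactor <- 100 * recPlddt[match(rec$resno, seq_len(R))]
  pep$bfactor <- 100 * pepPlddt[match(pep$resno, seq_len(P))]
  if (query@linkage == "separate") {
    st <- PepStructure("mock-model",
                       rbind(rec, within(pep, chain <- "B")),
                       seqres = list(A = model@receptorSeqres,
                                     B = model@peptideSeqres))
    plddt <- c(recPlddt, pepPlddt)
  } else {
    L <- query@linkerLength
    startCA <- unlist(rec[rec$resno == R & rec$atom == "CA",
                          c("x", "y", "z")])
    endCA <- unlist(pep[pep$resno == 1L & pep$atom == "CA",
                        c("x", "y", "z")])
    linkRows <- lapply(seq_len(L), function(i) {
      t <- i / (L + 1)
      pt <- (1 - t) * startCA + t * endCA + c(0, 15 * sin(pi * t), 0)
      m <- rbind(N = pt + c(0, 0, -0.4), CA = pt, C = pt + c(0, 0, 0.4),
                 O = pt + c(0, 0.8, 0.4))
      residueRows(m, "A", R + i, "GLY", bfactor = 30)
    })
    fusedPep <- pep
    fusedPep$chain <- "A"
    fusedPep$resno <- fusedPep$resno + R + L
    fused <- rbind(rec, do.call(rbind, linkRows), fusedPep)
    fused$seqidx <- fused$resno - 1L
    rownames(fused) <- NULL
    st <- PepStructure("mock-model", fused,
                       seqres = list(A = c(model@receptorSeqres,
                                           rep("GLY", L),
                                           model@peptideSeqres)))
    plddt <- c(recPlddt, rep(0.30, L), pepPlddt)
  }
  new("PredictedModel", structure = st, query = query, plddt = plddt)
}

#' Build the docking query matching a fixture native
#'
#' @param native a [SplitComplex-class] from [makeToyComplex()].
#' @param linkage `"linked"` or `"separate"`.
#' @param linkerLength linker glycines for linked mode (default 30).
#' @return a [DockingQuery-class].
#' @export
fixtureQuery <- function(native, linkage = c("linked", "separate"),
                         linkerLength = 30L) {
  linkage <- match.arg(linkage)
  recSeq <- paste(STANDARD_AA3[native@receptorSeqres], collapse = "")
  pepSeq <- paste(STANDARD_AA3[native@peptideSeqres], collapse = "")
  if (linkage == "linked") buildLinkedQuery(recSeq, pepSeq, linkerLength)
  else buildSeparateQuery(recSeq, pepSeq)
}

#' Write a fixture bundle: PDB plus ground-truth JSON
#'
#' @param native a fixture [SplitComplex-class] or crystal
#'   [PepStructure-class] carrying a `groundTruth` attribute.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return paths of the written files, invisibly.
#' @export
writeFixtureBundle <- function(native, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdbPath <- file.path(dir, paste0(name, ".pdb"))
  if (is(native, "SplitComplex"))
    writeSplitComplex(native, pdbPath, entryId = name)
  else
    writeStructurePDB(native, pdbPath)
  truthPath <- file.path(dir, paste0(name, ".truth.json"))
  jsonlite::write_json(attr(native, "groundTruth"), truthPath,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(pdb = pdbPath, truth = truthPath))
}
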