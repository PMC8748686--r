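# Shared helpers: random point clouds, random rigid transforms, and
# brute-force oracles written as explicit loops, independent of the
# vectorised implementations they check.

randCloud <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), n, 3)
}

# uniform-ish random proper rotation + translation
randTransform <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

applyRigid <- function(tr, coords) {
  coords %*% t(tr$R) + matrix(tr$t, nrow(coords), 3, byrow = TRUE)
}

rigidSplit <- function(split, tr) {
  for (s in c("receptor", "peptide")) {
    a <- slot(split, s)
    xyz <- applyRigid(tr, cbind(a$x, a$y, a$z))
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    slot(split, s) <- a
  }
  split
}

# brute-force interface rule: explicit double loop over residues
oracleInterface <- function(native, cutoff = 8.0) {
  repAtom <- function(atoms, resno) {
    sel <- which(atoms$resno == resno)
    cb <- sel[atoms$atom[sel] == "CB"]
    j <- if (length(cb)) cb[1] else sel[atoms$atom[sel] == "CA"][1]
    c(atoms$x[j], atoms$y[j], atoms$z[j])
  }
  rec <- receptorAtoms(native); pep <- peptideAtoms(native)
  recIf <- integer(0); pepIf <- integer(0)
  for (rn in unique(rec$resno)) for (pn in unique(pep$resno)) {
    if (sqrt(sum((repAtom(rec, rn) - repAtom(pep, pn))^2)) <= cutoff) {
      recIf <- c(recIf, rec$seqidx[rec$resno == rn][1])
      pepIf <- c(pepIf, pep$seqidx[pep$resno == pn][1])
    }
  }
  list(peptideIf = sort(unique(pepIf)), receptorIf = sort(unique(recIf)))
}

# brute-force residue-residue contact set at a heavy-atom cutoff
oracleContacts <- function(split, cutoff = 5.0) {
  rec <- receptorAtoms(split); pep <- peptideAtoms(split)
  rec <- rec[rec$element != "H", ]; pep <- pep[pep$element != "H", ]
  keys <- character(0)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(pep))) {
    d <- sqrt((rec$x[i] - pep$x[j])^2 + (rec$y[i] - pep$y[j])^2 +
                (rec$z[i] - pep$z[j])^2)
    if (d <= cutoff)
      keys <- c(keys, paste(rec$seqidx[i], pep$seqidx[j], sep = "|"))
  }
  sort(unique(keys))
}

# brute-force pocket rule: explicit loops over backbone atoms
oraclePocket <- function(split, cutoff = 8.0) {
  bb <- c("N", "CA", "C", "O")
  rec <- receptorAtoms(split); pep <- peptideAtoms(split)
  rec <- rec[rec$atom %in% bb, ]; pep <- pep[pep$atom %in% bb, ]
  hits <- integer(0)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(pep))) {
      d <- sqrt((rec$x[i] - pep$x[j])^2 + (rec$y[i] - pep$y[j])^2 +
                  (rec$z[i] - pep$z[j])^2)
      if (d <= cutoff) { hits <- c(hits, rec$seqidx[i]); break }
    }
  }
  sort(unique(hits))
}

# minimal hand-built two-residue chains for boundary-geometry tests: one
# residue per chain with CA at the origin of each and CB at a chosen offset
twoResidueComplex <- function(cbGap) {
  mk <- function(chain, resno, xoff, cbx) {
    data.frame(chain = chain, resno = resno, inscode = "",
               resname = "ALA", seqidx = resno - 1L,
               atom = c("N", "CA", "C", "O", "CB"), element = c("N", "C",
               "C", "O", "C"),
               x = xoff + c(-1.2, 0, 1.2, 1.8, cbx), y = c(0.5, 0, -0.5,
               0.6, 0), z = 0,
               occ = 1, bfactor = 50, altloc = "", stringsAsFactors = FALSE)
  }
  SplitComplex(mk("A", 1L, 0, 1.0), mk("B", 1L, cbGap + 1.0, 0),
               receptorSeqres = "ALA", peptideSeqres = "ALA")
}
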