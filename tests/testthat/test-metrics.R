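test_that("the interface rule is a sharp 8.0 Angstrom boundary", {
  just_in <- twoResidueComplex(7.9)
  ifc <- defineInterface(just_in)
  expect_equal(peptideInterface(ifc), 0L)
  expect_equal(receptorInterface(ifc), 0L)
  just_out <- twoResidueComplex(8.1)
  expect_warning(ifc2 <- defineInterface(just_out), "empty interface")
  expect_length(peptideInterface(ifc2), 0L)
})

test_that("interface, contacts and pocket match brute-force oracles", {
  for (seed in 1:25) {
    set.seed(seed)
    nat <- makeToyComplex(receptorLen = 32L, peptideLen = 5L,
                          grooveOffset = runif(1, 3, 9), seed = seed)
    ifc <- suppressWarnings(defineInterface(nat))
    oracle <- oracleInterface(nat)
    expect_identical(peptideInterface(ifc), oracle$peptideIf)
    expect_identical(receptorInterface(ifc), oracle$receptorIf)
    expect_identical(pocketResidues(nat), oraclePocket(nat))
    expect_identical(sort(PepDockBench:::contactKeys(nat, 5.0)),
                     oracleContacts(nat, 5.0))
  }
})

test_that("a perfect model scores perfectly on every metric", {
  nat <- makeToyComplex(seed = 1)
  ifc <- defineInterface(nat)
  fpd <- fpdRmsdSuite(nat, nat, ifc)
  expect_true(all(abs(fpd) < 1e-9))
  capri <- capriMetrics(nat, nat, ifc)
  expect_lt(capri[["Irms"]], 1e-9)
  expect_lt(capri[["Lrms"]], 1e-9)
  expect_equal(capri[["Fnat"]], 1.0)
  expect_equal(pocketRecovery(nat, nat), 1.0)
  expect_lt(chainRmsd(peptideAtoms(nat), peptideAtoms(nat)), 1e-9)
})

test_that("a pure peptide translation gives its norm as interface RMSD", {
  nat <- makeToyComplex(seed = 2)
  ifc <- defineInterface(nat)
  model <- perturbModel(nat, peptideShift = c(3, 0, 0))
  fpd <- fpdRmsdSuite(nat, model, ifc)
  expect_equal(fpd[["rmsBB_if"]], 3.0, tolerance = 1e-9)
  expect_equal(fpd[["rmsALL_if"]], 3.0, tolerance = 1e-9)
  # Lrms is receptor-fitted peptide backbone RMSD: also exactly 3
  capri <- capriMetrics(nat, model, ifc)
  expect_equal(capri[["Lrms"]], 3.0, tolerance = 1e-9)
})

test_that("all metrics are invariant under rigid motion of the model", {
  nat <- makeToyComplex(seed = 3)
  ifc <- defineInterface(nat)
  model <- perturbModel(nat, peptideShift = c(1.5, 1, 0), noiseSigma = 0.3,
                        seed = 11)
  base <- evaluateComplex(nat, model)
  for (seed in 1:5) {
    moved <- rigidSplit(model, randTransform(seed + 70))
    res <- evaluateComplex(nat, moved)
    for (col in c("rmsBB_if", "rmsALL_if", "rmsBB_allIF", "rmsALL_allIF",
                  "Irms", "Lrms", "Fnat", "DockQ", "receptor_rmsd",
                  "peptide_rmsd", "pocket_recovery"))
      expect_equal(res[[col]], base[[col]], tolerance = 1e-6)
    expect_identical(res$failed, base$failed)
  }
})

test_that("backbone and heavy-atom interface RMSDs agree without side chains", {
  nat <- makeToyComplex(seed = 4)
  model <- perturbModel(nat, peptideShift = c(2, -1, 1), noiseSigma = 0.2,
                        seed = 5)
  stripCB <- function(sp) {
    sp@receptor <- sp@receptor[sp@receptor$atom != "CB", ]
    sp@peptide <- sp@peptide[sp@peptide$atom != "CB", ]
    sp
  }
  natBB <- stripCB(nat); modBB <- stripCB(model)
  ifc <- defineInterface(nat)
  fpd <- fpdRmsdSuite(natBB, modBB, ifc)
  expect_equal(fpd[["rmsBB_if"]], fpd[["rmsALL_if"]])
  expect_equal(fpd[["rmsBB_allIF"]], fpd[["rmsALL_allIF"]])
  expect_true(all(fpd >= 0))
})

test_that("Fnat counts native contact recovery against the oracle", {
  nat <- makeToyComplex(seed = 5)
  ifc <- defineInterface(nat)
  far <- perturbModel(nat, peptideShift = c(60, 0, 0))
  expect_equal(capriMetrics(nat, far, ifc)[["Fnat"]], 0.0)
  for (seed in 1:10) {
    set.seed(seed)
    model <- perturbModel(nat, peptideShift = runif(3, -2, 2), seed = seed)
    natC <- oracleContacts(nat, 5.0)
    modC <- oracleContacts(model, 5.0)
    expect_equal(capriMetrics(nat, model, ifc)[["Fnat"]],
                 length(intersect(natC, modC)) / length(natC))
  }
})

test_that("DockQ evaluates its closed form and is monotone in the RMSDs", {
  expect_equal(dockqScore(1, 0, 0), 1.0)
  expect_equal(dockqScore(0, 8.5, 1.5), 1 / 3)
  expect_equal(dockqScore(0.5, 2, 1),
               (0.5 + 1 / (1 + (1 / 1.5)^2) + 1 / (1 + (2 / 8.5)^2)) / 3)
  # limit: DockQ -> Fnat/3 as both RMSDs grow
  expect_equal(dockqScore(0.6, 1e6, 1e6), 0.2, tolerance = 1e-9)
  set.seed(1)
  for (i in 1:20) {
    f <- runif(1); l <- runif(1, 0, 20); ir <- runif(1, 0, 10)
    eps <- 0.1
    expect_lt(dockqScore(f, l + eps, ir), dockqScore(f, l, ir))
    expect_lt(dockqScore(f, l, ir + eps), dockqScore(f, l, ir))
    expect_gt(dockqScore(min(1, f + eps), l, ir), dockqScore(f, l, ir))
  }
  expect_error(dockqScore(1.2, 0, 0), "Fnat")
  expect_error(dockqScore(0.5, -1, 0), "non-negative")
})

test_that("per-residue RMSD skips native-unresolved residues, ignores OXT", {
  nat <- makeToyComplex(receptorLen = 34L, peptideLen = 6L, seed = 6)
  model <- perturbModel(nat, peptideShift = c(1, 0, 0))
  pr <- perResidueRmsd(nat, model)
  expect_equal(nrow(pr), 6L)
  expect_true(all(abs(pr$rmsd - 1.0) < 1e-9))
  # native missing one residue -> SKIPPED
  nat2 <- nat
  nat2@peptide <- nat2@peptide[nat2@peptide$resno != 3, ]
  pr2 <- perResidueRmsd(nat2, model)
  expect_true(pr2$skipped[pr2$seqidx == 2])
  expect_true(is.na(pr2$rmsd[pr2$seqidx == 2]))
  expect_false(any(pr2$skipped[pr2$seqidx != 2]))
  # an OXT present only in the native is excluded pairwise
  nat3 <- nat
  oxt <- nat3@peptide[nat3@peptide$resno == 6 &
                        nat3@peptide$atom == "C", ]
  oxt$atom <- "OXT"; oxt$element <- "O"; oxt$x <- oxt$x + 30
  nat3@peptide <- rbind(nat3@peptide, oxt)
  pr3 <- perResidueRmsd(nat3, model)
  expect_true(all(abs(pr3$rmsd - 1.0) < 1e-9))
})

test_that("atom-weighted per-residue RMSDs pool to the unfitted peptide RMSD", {
  nat <- makeToyComplex(seed = 7)
  model <- perturbModel(nat, peptideShift = c(2, 1, -1), noiseSigma = 0.4,
                        seed = 3)
  pr <- perResidueRmsd(nat, model)
  pooled <- sqrt(sum(pr$rmsd^2 * pr$n_atoms) / sum(pr$n_atoms))
  fit <- PepDockBench:::receptorSuperpose(nat, model)
  moved <- PepDockBench:::transformSplit(model, fit)
  pc <- PepDockBench:::pairedCoords(nat@peptide, moved@peptide)
  expect_equal(pooled, coordRmsd(pc$a, pc$b), tolerance = 1e-9)
})

test_that("pocket recovery spans the full range", {
  nat <- makeToyComplex(seed = 8)
  expect_equal(pocketRecovery(nat, nat), 1.0)
  expect_equal(pocketRecovery(nat, makeThrownModel(nat)), 0.0)
  # sliding the peptide along the receptor covers part of the pocket
  slid <- perturbModel(nat, peptideShift = c(0, 0, 14))
  frac <- pocketRecovery(nat, slid)
  expect_gt(frac, 0); expect_lt(frac, 1)
  natPocket <- pocketResidues(nat)
  expect_equal(frac,
               length(intersect(natPocket, pocketResidues(slid))) /
                 length(natPocket))
  farNat <- makeToyComplex(grooveOffset = 60, seed = 8)
  expect_error(pocketRecovery(farNat, nat), "empty")
})

test_that("chain RMSD removes rigid motion and matches an external fit", {
  nat <- makeToyComplex(seed = 9)
  pep <- peptideAtoms(nat)
  expect_lt(chainRmsd(pep, pep), 1e-9)
  moved <- rigidSplit(nat, randTransform(3))
  expect_lt(chainRmsd(pep, peptideAtoms(moved)), 1e-7)
  # noisy chain: compare against bio3d's superposition as independent oracle
  noisy <- perturbModel(nat, noiseSigma = 1.0, seed = 13)
  ours <- chainRmsd(pep, peptideAtoms(noisy))
  a <- as.vector(t(PepDockBench:::atomCoords(pep)))
  b <- as.vector(t(PepDockBench:::atomCoords(peptideAtoms(noisy))))
  fitted <- suppressWarnings(bio3d::fit.xyz(a, b))
  oracle <- sqrt(mean(colSums(matrix((fitted - a)^2, nrow = 3))))
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("pocket occupancy measures candidate coverage of the native pocket", {
  nat <- makeToyComplex(seed = 10)
  expect_equal(pocketOccupancy(nat, peptideAtoms(nat)), 1.0)
  far <- peptideAtoms(nat); far$x <- far$x + 100
  expect_equal(pocketOccupancy(nat, far), 0.0)
  # a half-length candidate occupies only part of the pocket
  pep <- peptideAtoms(nat)
  half <- pep[pep$resno <= max(pep$resno) / 2, ]
  occ <- pocketOccupancy(nat, half)
  expect_gt(occ, 0); expect_lt(occ, 1)
})
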