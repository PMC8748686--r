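test_that("fixture generation is a pure function of (spec, seed)", {
  a <- makeToyComplex(40L, 8L, "extended", 5.0, seed = 1)
  b <- makeToyComplex(40L, 8L, "extended", 5.0, seed = 1)
  expect_identical(a@receptor, b@receptor)
  expect_identical(a@peptide, b@peptide)
  expect_identical(attr(a, "groundTruth"), attr(b, "groundTruth"))
  c_ <- makeToyComplex(40L, 8L, "extended", 5.0, seed = 2)
  expect_false(identical(a@receptorSeqres, c_@receptorSeqres))
})

test_that("a distant groove yields an empty interface by construction", {
  far <- makeToyComplex(grooveOffset = 50, seed = 1)
  truth <- attr(far, "groundTruth")
  expect_length(truth$interface$peptideIf, 0L)
  expect_length(truth$pocket, 0L)
  expect_warning(defineInterface(far), "empty interface")
})

test_that("the recorded interface matches the constructed geometry", {
  for (seed in 1:10) {
    nat <- makeToyComplex(receptorLen = 33L, peptideLen = 6L, seed = seed)
    truth <- attr(nat, "groundTruth")
    ifc <- defineInterface(nat)
    expect_identical(peptideInterface(ifc), truth$interface$peptideIf)
    expect_identical(receptorInterface(ifc), truth$interface$receptorIf)
    expect_identical(pocketResidues(nat), truth$pocket)
  }
})

test_that("helical peptides are supported", {
  nat <- makeToyComplex(peptideGeometry = "helix", seed = 3)
  expect_false(detectFailure(nat))
  expect_gt(length(attr(nat, "groundTruth")$interface$peptideIf), 0L)
})

test_that("pure translations perturb by exactly their norm", {
  nat <- makeToyComplex(seed = 2)
  m <- perturbModel(nat, peptideShift = c(3, 0, 0))
  expect_equal(fpdRmsdSuite(nat, m, defineInterface(nat))[["rmsBB_if"]],
               3.0, tolerance = 1e-9)
  same <- perturbModel(nat)
  expect_true(all(abs(unlist(evaluateComplex(nat, same)[
    c("rmsBB_if", "Irms", "Lrms")])) < 1e-9))
  expect_identical(receptorAtoms(m)$x, receptorAtoms(nat)$x)
})

test_that("noise-only models land in the estimator band of the target RMSD", {
  nat <- makeToyComplex(seed = 4)
  sigma <- 0.5
  nAtoms <- nrow(peptideAtoms(nat))
  vals <- vapply(1:60, function(s) {
    m <- perturbModel(nat, noiseSigma = sigma, seed = s)
    pn <- peptideAtoms(nat); pm <- peptideAtoms(m)
    sqrt(mean((pn$x - pm$x)^2 + (pn$y - pm$y)^2 + (pn$z - pm$z)^2))
  }, numeric(1))
  # unfitted RMSD of isotropic noise: E[rmsd^2] = 3 sigma^2
  expected <- sigma * sqrt(3)
  se <- expected / sqrt(2 * length(vals) * nAtoms)
  expect_lt(abs(mean(vals) - expected), 5 * se + 0.01)
})

test_that("crystal fixtures realise their target contact fraction", {
  nat <- makeToyComplex(receptorLen = 35L, peptideLen = 5L, seed = 5)
  cf <- makeCrystalFixture(nat, 0.2)
  truth <- attr(cf, "groundTruth")
  expect_equal(truth$fraction, 0.2)
  expect_length(truth$contactResidues, 1L)
  cf0 <- makeCrystalFixture(nat, 0)
  expect_equal(attr(cf0, "groundTruth")$fraction, 0)
  expect_error(makeCrystalFixture(nat, 1.5), "\\[0,1\\]")
})

test_that("synthetic confidence maps displacement monotonically", {
  d <- c(0, 1, 2.5, 5, 20)
  p <- synthConfidence(d)
  expect_equal(p[1], 1.0)
  expect_equal(p[3], 0.7)        # 2.5 A displacement sits at the cutoff
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  # noiseless mapping gives perfect separation at matched cutoffs
  set.seed(9)
  disp <- runif(200, 0, 6)
  stats <- plddtAccuracyStats(data.frame(plddt = synthConfidence(disp),
                                         rmsd = disp))
  expect_equal(stats$fp, 0L)
  expect_equal(stats$fn + stats$tp, sum(disp <= 2.5))
  # bounded noise stays in range
  noisy <- synthConfidence(runif(100, 0, 10), noise = 0.2, seed = 2)
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("synthetic alanine scans honour their hotspot labels", {
  tbl <- synthAlascan(50, hotspotFraction = 0.4, noiseSigma = 0, seed = 3)
  expect_equal(sum(tbl$isHotspot), 20L)
  expect_identical(tbl$native$ddG >= 1.5, tbl$isHotspot)
  r <- hotspotConfusion(tbl$model, tbl$native)
  expect_equal(r$fp + r$fn, 0L)
  expect_equal(r$spearman_rho, 1.0)
  for (seed in 1:10) {
    tbl <- synthAlascan(30, 0.3, noiseSigma = 0.4, seed = seed)
    r <- hotspotConfusion(tbl$model, tbl$native)
    expect_equal(r$tp + r$fn, sum(tbl$isHotspot))
    expect_equal(r$tp + r$fp, sum(tbl$model$ddG >= 1.5))
  }
})

test_that("mock predictor behaviors produce the expected model quality", {
  nat <- makeToyComplex(receptorLen = 33L, peptideLen = 5L, seed = 6)
  qLinked <- fixtureQuery(nat, "linked")
  perfect <- splitFusedModel(mockPredictor(qLinked, nat, "perfect"))
  res <- evaluateComplex(nat, perfect)
  expect_lt(res$rmsBB_if, 1e-9)
  expect_equal(res$DockQ, 1.0, tolerance = 1e-9)
  expect_false(res$failed)
  thrown <- splitFusedModel(mockPredictor(qLinked, nat, "thrown"))
  resT <- evaluateComplex(nat, thrown)
  expect_true(resT$failed)
  expect_equal(resT$Fnat, 0.0)
  expect_equal(resT$pocket_recovery, 0.0)
  # linked-mode output length is R + 30 + P
  model <- mockPredictor(qLinked, nat, "perfect")
  expect_equal(nrow(uniqueResidues(model@structure@atoms)), 33L + 30L + 5L)
  expect_length(model@plddt, 68L)
})

test_that("fixture bundles round-trip through PDB and record ground truth", {
  nat <- makeToyComplex(receptorLen = 33L, peptideLen = 5L, seed = 7)
  dir <- withr::local_tempdir()
  paths <- writeFixtureBundle(nat, dir, "toy7")
  st <- readStructure(paths[["pdb"]])
  expect_identical(chainIds(st), c("A", "B"))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$interface$peptideIf,
               attr(nat, "groundTruth")$interface$peptideIf)
  rt <- asSplitComplex(st, "A", "B")
  ifc <- defineInterface(rt)
  expect_equal(peptideInterface(ifc),
               attr(nat, "groundTruth")$interface$peptideIf)
})
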