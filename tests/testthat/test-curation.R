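# build a candidate entry from a toy complex, optionally tweaking sizes
toyEntry <- function(id = "e1", receptorLen = 35L, peptideLen = 6L,
                     seed = 1, domainLabel = "fam.1", resolution = 2.0,
                     grooveOffset = 4.0, ...) {
  nat <- makeToyComplex(receptorLen = receptorLen, peptideLen = peptideLen,
                        grooveOffset = grooveOffset, seed = seed)
  st <- PepDockBench:::splitToStructure(nat, id)
  candidateEntry(id, st, "A", "B", domainLabel = domainLabel,
                 resolution = resolution, ...)
}

test_that("the length filter enforces its stated boundaries", {
  expect_true(lengthFilter(toyEntry(receptorLen = 31L, peptideLen = 4L)))
  expect_false(lengthFilter(toyEntry(receptorLen = 30L, peptideLen = 6L)))
  expect_true(lengthFilter(toyEntry(peptideLen = 25L)))
  expect_false(lengthFilter(toyEntry(peptideLen = 26L)))
  expect_false(lengthFilter(toyEntry(peptideLen = 3L)))
  # peptide of 10 with only 2 resolved fails the resolved-count rule
  e <- toyEntry(peptideLen = 10L)
  atoms <- e@structure@atoms
  e@structure@atoms <- atoms[atoms$chain != "B" |
                               atoms$resno %in% c(1, 2), ]
  expect_false(lengthFilter(e))
  # 3 resolved passes
  e@structure@atoms <- atoms[atoms$chain != "B" |
                               atoms$resno %in% c(1, 2, 3), ]
  expect_true(lengthFilter(e))
})

test_that("the contact filter needs two peptide residues within 4 A", {
  expect_true(contactFilter(toyEntry()))
  expect_false(contactFilter(toyEntry(grooveOffset = 50)))
  # brute-force count agreement on random groove offsets
  for (seed in 1:15) {
    set.seed(seed)
    e <- toyEntry(id = paste0("r", seed), seed = seed,
                  grooveOffset = runif(1, 3, 7))
    rec <- chainAtoms(e@structure, "A"); pep <- chainAtoms(e@structure, "B")
    count <- 0L
    for (rn in unique(pep$resno)) {
      sel <- pep$resno == rn
      mind <- Inf
      for (i in which(sel))
        mind <- min(mind, sqrt((rec$x - pep$x[i])^2 +
                                 (rec$y - pep$y[i])^2 +
                                 (rec$z - pep$z[i])^2))
      if (mind <= 4.0) count <- count + 1L
    }
    expect_identical(
      PepDockBench:::countContactingPeptideResidues(e, 4.0), count)
    expect_identical(contactFilter(e), count >= 2L)
  }
})

test_that("the UNK filter reads the peptide SEQRES only", {
  e <- toyEntry()
  expect_true(unkFilter(e))
  e@structure@seqres$B[2] <- "UNK"
  expect_false(unkFilter(e))
  e2 <- toyEntry()
  e2@structure@seqres$A[5] <- "UNK"   # receptor UNK is tolerated
  expect_true(unkFilter(e2))
})

test_that("symmetry filtering is inclusive at the 20% boundary", {
  nat <- makeToyComplex(receptorLen = 35L, peptideLen = 5L, seed = 3)
  cf <- makeCrystalFixture(nat, 0.2)
  e <- candidateEntry("x1", cf, "A", "B")
  expect_equal(symmetryContactFraction(e), 0.2)
  expect_false(symmetryFilter(e))            # "at least 20%" rejects
  expect_true(symmetryFilter(e, threshold = 0.25))
  cf0 <- makeCrystalFixture(nat, 0)
  e0 <- candidateEntry("x0", cf0, "A", "B")
  expect_equal(symmetryContactFraction(e0), 0.0)
  expect_true(symmetryFilter(e0))
  # no cell: fraction 0 with a warning
  noCell <- candidateEntry("x2", PepDockBench:::splitToStructure(nat),
                           "A", "B")
  expect_warning(f <- symmetryContactFraction(noCell), "no cell")
  expect_equal(f, 0)
})

test_that("symmetry-contact fractions agree with ground truth across targets", {
  nat <- makeToyComplex(receptorLen = 35L, peptideLen = 10L, seed = 4)
  for (target in c(0, 0.2, 0.5, 1)) {
    cf <- makeCrystalFixture(nat, target)
    truth <- attr(cf, "groundTruth")$fraction
    expect_equal(truth, ceiling(target * 10) / 10)
    e <- candidateEntry("t", cf, "A", "B")
    expect_equal(symmetryContactFraction(e), truth)
  }
})

test_that("domain deduplication keeps the best-resolution representative", {
  entries <- list(
    toyEntry("a1", domainLabel = "famA", resolution = 2.5),
    toyEntry("a2", domainLabel = "famA", resolution = 1.8),
    toyEntry("a3", domainLabel = "famA", resolution = 1.8),
    toyEntry("b1", domainLabel = "famB", resolution = 3.0))
  kept <- dedupeByDomain(entries)
  ids <- vapply(kept, function(e) e@entryId, character(1))
  expect_setequal(ids, c("a2", "b1"))   # best resolution, tie -> smaller id
  kept2 <- dedupeByDomain(entries, exclude = "famA")
  expect_equal(vapply(kept2, function(e) e@entryId, character(1)), "b1")
  # survivor count equals distinct non-excluded labels
  expect_length(dedupeByDomain(entries), 2L)
  unlabelled <- toyEntry("u1", domainLabel = NA)
  expect_error(dedupeByDomain(c(entries, unlabelled)), "without domain")
})

test_that("the curation chain reports per-filter outcomes for every entry", {
  nat5 <- makeToyComplex(receptorLen = 35L, peptideLen = 5L, seed = 5)
  crystalBad <- candidateEntry("sym_fail", makeCrystalFixture(nat5, 0.4),
                               "A", "B", domainLabel = "fam.sym",
                               resolution = 2.0)
  entries <- list(
    toyEntry("ok1", domainLabel = "fam.ok1"),
    toyEntry("len_fail", receptorLen = 30L, domainLabel = "fam.len"),
    toyEntry("contact_fail", grooveOffset = 50, domainLabel = "fam.con"),
    crystalBad,
    toyEntry("ptm1", domainLabel = "fam.ptm", ptmLig = TRUE))
  unkBad <- toyEntry("unk_fail", domainLabel = "fam.unk")
  unkBad@structure@seqres$B[1] <- "UNK"
  entries <- c(entries, unkBad)
  res <- suppressWarnings(curateEntries(entries))
  rep_ <- res$reports
  expect_equal(nrow(rep_), 6L)
  expect_false(rep_$length[rep_$entry_id == "len_fail"])
  expect_false(rep_$contact[rep_$entry_id == "contact_fail"])
  expect_false(rep_$symmetry[rep_$entry_id == "sym_fail"])
  expect_false(rep_$unk[rep_$entry_id == "unk_fail"])
  # each engineered entry fails exactly one filter
  flagCols <- c("length", "unk", "range_agreement", "contact", "symmetry")
  fails <- rowSums(!rep_[, flagCols])
  expect_equal(fails[rep_$entry_id %in%
                       c("len_fail", "contact_fail", "sym_fail",
                         "unk_fail")], rep(1, 4), ignore_attr = TRUE)
  # pass_filters is the conjunction of the per-filter flags
  expect_equal(rep_$pass_filters,
               apply(rep_[, flagCols], 1, all))
  # PTM/ligand entries are set aside, not accepted
  expect_equal(vapply(res$setAside, function(e) e@entryId, character(1)),
               "ptm1")
  expect_equal(vapply(res$accepted, function(e) e@entryId, character(1)),
               "ok1")
})

test_that("the accepted set does not depend on filter evaluation order", {
  entries <- list(
    toyEntry("p1", domainLabel = "f1"),
    toyEntry("p2", receptorLen = 28L, domainLabel = "f2"),
    toyEntry("p3", grooveOffset = 50, domainLabel = "f3"),
    toyEntry("p4", domainLabel = "f4"))
  filters <- list(lengthFilter, unkFilter, rangeAgreementFilter,
                  function(e) contactFilter(e),
                  function(e) suppressWarnings(symmetryFilter(e)))
  set.seed(23)
  base <- NULL
  for (perm in 1:5) {
    ord <- sample(length(filters))
    surviving <- Filter(function(e)
      all(vapply(filters[ord], function(f) f(e), logical(1))), entries)
    ids <- vapply(surviving, function(e) e@entryId, character(1))
    if (is.null(base)) base <- ids
    expect_identical(ids, base)
  }
  chain <- suppressWarnings(curateEntries(entries))
  expect_setequal(vapply(chain$accepted, function(e) e@entryId,
                         character(1)), base)
})
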