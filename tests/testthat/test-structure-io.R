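toyStructure <- function(seed = 1, cell = numeric(0), symOps = list()) {
  nat <- makeToyComplex(receptorLen = 34L, peptideLen = 5L, seed = seed)
  PepDockBench:::splitToStructure(nat, "toy", cell = cell, symOps = symOps)
}

test_that("PDB round-trip preserves the full hierarchy", {
  st <- toyStructure(1, cell = c(40, 50, 60, 90, 90, 120),
                     symOps = list(PepDockBench:::identityOp(),
                                   parseSymopXyz("-X,Y+1/2,-Z")))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(st, path)
  rt <- readStructure(path)
  expect_identical(chainIds(rt), c("A", "B"))
  expect_identical(nrow(rt@atoms), nrow(st@atoms))
  expect_lt(max(abs(PepDockBench:::atomCoords(rt@atoms) -
                      PepDockBench:::atomCoords(st@atoms))), 1e-3)
  expect_equal(rt@atoms$bfactor, st@atoms$bfactor, tolerance = 1e-6)
  expect_identical(rt@atoms$seqidx, st@atoms$seqidx)
  expect_equal(rt@cell, st@cell)
  expect_equal(length(rt@symOps), 2L)
  expect_equal(formatSymopXyz(rt@symOps[[2]]), "-X,Y+1/2,-Z")
  expect_identical(chainSeqres(rt, "A"), chainSeqres(st, "A"))
})

test_that("mmCIF carries the identical hierarchy as PDB", {
  st <- toyStructure(2, cell = c(40, 50, 60, 90, 90, 90),
                     symOps = list(PepDockBench:::identityOp()))
  pdbPath <- withr::local_tempfile(fileext = ".pdb")
  cifPath <- withr::local_tempfile(fileext = ".cif")
  writeStructurePDB(st, pdbPath)
  writeStructureCIF(st, cifPath)
  a <- readStructure(pdbPath)
  b <- readStructure(cifPath)
  expect_identical(chainIds(a), chainIds(b))
  expect_identical(a@atoms$atom, b@atoms$atom)
  expect_identical(a@atoms$resname, b@atoms$resname)
  expect_identical(a@atoms$seqidx, b@atoms$seqidx)
  expect_lt(max(abs(PepDockBench:::atomCoords(a@atoms) -
                      PepDockBench:::atomCoords(b@atoms))), 1e-3)
  expect_equal(a@atoms$bfactor, b@atoms$bfactor)
  expect_equal(a@cell, b@cell)
  expect_identical(a@seqres, b@seqres)
})

test_that("files without SEQRES fall back to resolved residues", {
  st <- toyStructure(3)
  st@seqres <- list()
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(st, path)
  rt <- readStructure(path)
  expect_length(chainSeqres(rt, "A"), 0)
  seq <- extractSequence(rt, "A", source = "resolved")
  expect_equal(nchar(seq), 34L)
  # fallback seqidx: residue numbers relative to the first resolved residue
  expect_identical(rt@atoms$seqidx, st@atoms$seqidx)
})

test_that("altloc reduction keeps the highest-occupancy conformer", {
  st <- toyStructure(4)
  atoms <- st@atoms
  dup <- atoms[atoms$resno == 1 & atoms$atom == "CA" &
                 atoms$chain == "A", ]
  atoms$altloc[atoms$resno == 1 & atoms$atom == "CA" &
                 atoms$chain == "A"] <- "A"
  atoms$occ[atoms$resno == 1 & atoms$atom == "CA" &
              atoms$chain == "A"] <- 0.4
  dup$altloc <- "B"; dup$occ <- 0.6; dup$x <- dup$x + 5
  st@atoms <- rbind(atoms[1, ], dup, atoms[-1, ])
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(st, path)
  rt <- readStructure(path)
  ca <- rt@atoms[rt@atoms$resno == 1 & rt@atoms$atom == "CA" &
                   rt@atoms$chain == "A", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, dup$x, tolerance = 1e-3)   # the 0.6-occupancy copy
})

test_that("sequence cleaning removes UNK and terminal modifications", {
  st <- toyStructure(5)
  st@seqres$B <- c("ACE", "ALA", "GLY", "UNK", "LYS", "NH2")
  expect_equal(extractSequence(st, "B"), "AGK")
  st@seqres$B <- c("ALA", "MSE", "LYS")
  expect_equal(extractSequence(st, "B"), "AMK")   # MSE maps to parent MET
  st@seqres$B <- rep(names(PepDockBench:::STANDARD_AA3)[1:20], 1)
  expect_equal(extractSequence(st, "B"),
               paste(unname(PepDockBench:::STANDARD_AA3), collapse = ""))
  st@seqres$B <- c("ACE", "UNK", "NH2")
  expect_error(extractSequence(st, "B"), "empty")
})

test_that("confidence extraction normalises scale and falls back to CA", {
  st <- toyStructure(6)
  st@atoms$bfactor <- 70.0
  pl <- extractPlddt(st)
  expect_true(all(abs(unlist(pl) - 0.70) < 1e-12))
  st@atoms$bfactor <- 0.91
  expect_true(all(abs(unlist(extractPlddt(st)) - 0.91) < 1e-12))
  # scale detection is idempotent: re-extracting scaled values changes nothing
  st@atoms$bfactor <- 0.70
  expect_true(all(abs(unlist(extractPlddt(st)) - 0.70) < 1e-12))
  # mixed per-atom values beyond tolerance: CA value with a warning
  st@atoms$bfactor <- 50
  sel <- st@atoms$chain == "B" & st@atoms$resno == 1
  st@atoms$bfactor[sel] <- c(10, 80, 30, 40, 50)  # CA is the second atom
  expect_warning(pl <- extractPlddt(st), "CA")
  expect_equal(pl$B[1], 0.80)
  st@atoms$bfactor <- 150
  expect_error(extractPlddt(st), "outside")
})

test_that("residue mapping pairs by SEQRES index and drops unresolved", {
  nat <- makeToyComplex(receptorLen = 34L, peptideLen = 10L, seed = 7)
  pep <- peptideAtoms(nat)
  expect_equal(nrow(mapResidues(pep, pep)), 10L)
  # native missing residues 3-4
  natPep <- pep[!pep$resno %in% c(3, 4), ]
  m <- mapResidues(pep, natPep)
  expect_equal(nrow(m), 8L)
  expect_false(any(m$seqidx %in% c(2L, 3L)))
  # symmetric cardinality
  expect_equal(nrow(mapResidues(natPep, pep)), nrow(m))
  # model full SEQRES, native resolved 5..20 of 25
  nat25 <- makeToyComplex(receptorLen = 34L, peptideLen = 25L, seed = 8)
  pep25 <- peptideAtoms(nat25)
  natWindow <- pep25[pep25$resno %in% 5:20, ]
  expect_equal(nrow(mapResidues(pep25, natWindow)), 16L)
  expect_error(mapResidues(pep, natPep[0, ]), "no residues")
})

test_that("FASTA writing wraps at 80 columns and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(rec = strrep("MKVLAY", 20), pep = "PPGY")  # 120 aa + 4 aa
  writeFasta(seqs, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, ">")), 2L)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 80))
  rt <- readFasta(path)
  expect_identical(unname(rt), unname(seqs))
  expect_identical(names(rt), names(seqs))
  expect_error(writeFasta(character(0), path), "no records")
  expect_error(writeFasta(c(a = "AC DC"), path), "alphabetic")
})

test_that("symmetry operator strings round-trip through parsing", {
  ops <- c("X,Y,Z", "-X,Y+1/2,-Z", "-Y,X-Y,Z+1/3", "X+1/2,-Y+1/2,-Z")
  for (op in ops)
    expect_equal(formatSymopXyz(parseSymopXyz(op)), op)
  expect_error(parseSymopXyz("X,Y"), "bad symmetry")
})
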