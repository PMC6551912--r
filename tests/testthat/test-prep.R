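test_that("cleaning keeps the first alternate location, drops H and solvent", {
  raw <- readPDB(writeTempPDB(dimerPDBLines()))
  cl <- cleanStructure(raw)
  expect_equal(cl$report@removedAltloc, 1L)       # alt-loc B of Gly 1 N
  expect_equal(cl$report@removedHydrogens, 1L)
  expect_equal(cl$report@removedHetatm, 1L)       # ATOM-typed water
  at <- atomTable(cl$structure)
  nGly1 <- at[at$resSeq == 1 & at$chainId == "A" & at$name == "N", ]
  expect_equal(nrow(nGly1), 1)
  expect_equal(nGly1$x, 0.0)                      # first-listed location kept
  expect_false(any(at$element == "H"))
  expect_false(any(at$resName == "HOH"))
})

test_that("cleaning is idempotent and can keep hydrogens", {
  raw <- readPDB(writeTempPDB(dimerPDBLines()))
  once <- cleanStructure(raw)
  twice <- cleanStructure(once$structure)
  expect_identical(atomTable(twice$structure), atomTable(once$structure))
  expect_equal(twice$report@removedAltloc + twice$report@removedHydrogens +
               twice$report@removedHetatm, 0L)
  kept <- cleanStructure(raw, removeHydrogens = FALSE)
  expect_true(any(atomTable(kept$structure)$element == "H"))
})

test_that("nucleic-acid chains are rejected", {
  lines <- c("ATOM      1  P    DA A   1       0.000   0.000   0.000  1.00  0.00           P")
  expect_error(cleanStructure(readPDB(writeTempPDB(lines))), "nucleic")
})

test_that("a residue missing from one chain is deleted from all chains", {
  mk <- function(ch, resSeqs, yoff) {
    unlist(lapply(resSeqs, function(r) sprintf(
      "ATOM      1  %-3s GLY %s%4d      %6.3f  %6.3f   0.000  1.00  0.00           %s",
      c("N", "CA"), ch, r, r + c(0, 0.5), yoff, c("N", "C"))))
  }
  lines <- c(mk("A", c(55, 56, 57), 0), "TER", mk("B", c(55, 56), 1), "END")
  st <- readPDB(writeTempPDB(lines))
  hm <- harmonizeChains(st)
  at <- atomTable(hm$structure)
  expect_false(any(at$resSeq == 57))
  expect_equal(unname(lengths(peptideIndices(hm$structure))), c(4L, 4L))
  expect_true(57 %in% hm$report@prunedResidues$resSeq)
  expect_true(isPrepared(hm$structure))
})

test_that("an atom missing from one chain is deleted from all chains", {
  mk <- function(ch, names, yoff) sprintf(
    "ATOM      1  %-3s LYS %s  12      %6.3f  %6.3f   0.000  1.00  0.00           %s",
    names, ch, seq_along(names), yoff, substr(names, 1, 1))
  full <- c("N", "CA", "NZ")
  lines <- c(mk("A", full, 0), "TER", mk("B", full, 1), "TER",
             mk("C", c("N", "CA"), 2), "END")
  hm <- harmonizeChains(readPDB(writeTempPDB(lines)))
  at <- atomTable(hm$structure)
  expect_false("NZ" %in% at$name)
  expect_equal(sum(hm$report@prunedAtoms$name == "NZ"), 2L)
  expect_true(isPrepared(hm$structure))
})

test_that("declared REMARK 465 missing residues are honoured", {
  lines <- c("REMARK 465   M RES C SSSEQI",
             "REMARK 465     GLY A    57",
             sprintf("ATOM      1  CA  GLY %s%4d       1.000   %1d.000   0.000  1.00  0.00           C",
                     rep(c("A", "B"), each = 2), c(56, 57, 56, 57),
                     rep(0:1, each = 2)),
             "END")
  st <- readPDB(writeTempPDB(lines))
  hm <- harmonizeChains(st)
  expect_false(any(atomTable(hm$structure)$resSeq == 57))
})

test_that("harmonisation is idempotent and errors on irreconcilable chains", {
  gen <- syntheticHomomer(3, 4, noiseSigma = 0.1, seed = 2)
  once <- harmonizeChains(gen$structure)
  expect_identical(atomTable(once$structure), atomTable(gen$structure))
  expect_equal(nrow(once$report@prunedResidues), 0L)
  conflict <- c(
    "ATOM      1  CA  GLY A   5       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   5       1.000   1.000   0.000  1.00  0.00           C")
  expect_error(harmonizeChains(readPDB(writeTempPDB(conflict))), "5")
})

test_that("prepared structures have identical per-chain atom counts", {
  raw <- readPDB(writeTempPDB(dimerPDBLines()))
  pr <- prepareStructure(raw)
  lens <- lengths(peptideIndices(pr$structure))
  expect_equal(length(unique(lens)), 1L)
  expect_equal(unname(lens[1]), pr$report@finalPeptideLength)
  expect_equal(nAtoms(pr$structure),
               nPeptides(pr$structure) * pr$report@finalPeptideLength)
})
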