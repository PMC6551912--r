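test_that("initial axis regression: exact recovery, two-point fit, degenerate fallback", {
  gen <- syntheticHomomer(4, 6, noiseSigma = 0, seed = 13,
                          axis = c(2, 1, -2) / 3)
  part <- buildPartition(gen$structure)
  v <- initialAxis(gen$structure, part)
  expect_lt(angleToAxis(v, gen$groundTruth$axis), 1e-8)
  expect_false(attr(v, "degenerate"))

  # two classes: the line through the two class centroids exactly
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 1), c(3, 1, 1))
  st <- pointStructure(xyz, chainId = c("A", "B", "A", "B"),
                       resSeq = c(1, 1, 2, 2))
  v2 <- initialAxis(st, buildPartition(st))
  expect_lt(angleToAxis(v2, c(1, 1, 1)), 1e-12)

  # coincident centroids -> flagged fallback
  sq <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  st3 <- pointStructure(sq, chainId = c("A", "A", "B", "B"),
                        resSeq = c(1, 2, 1, 2))
  v3 <- initialAxis(st3, buildPartition(st3))
  expect_true(attr(v3, "degenerate"))

  # noisy recovery stays within a few degrees
  genN <- syntheticHomomer(3, 8, noiseSigma = 0.1, seed = 14)
  vN <- initialAxis(genN$structure, buildPartition(genN$structure))
  expect_lt(angleToAxis(vN, genN$groundTruth$axis), 5 * pi / 180)
})

test_that("solve is a fixed point on exact orbits and recovers the ground truth", {
  gen <- syntheticHomomer(4, 5, noiseSigma = 0, seed = 19,
                          axis = c(1, 2, 2) / 3)
  res <- solveCSM(gen$structure, "c4")
  expect_lte(csmValue(res), 1e-9)
  expect_lt(angleToAxis(symmetryAxis(res), gen$groundTruth$axis), 1e-6)
  expect_true(sameOrbit(peptidePermutation(res), gen$groundTruth$orbitPerm))
  expect_true(res@converged)
  expect_lte(res@iterations, 4)
})

test_that("solve is deterministic given structure, group and config", {
  gen <- syntheticHomomer(3, 6, noiseSigma = 0.3, seed = 7)
  cfg <- csmConfig(restarts = 4L, seed = 99L)
  r1 <- solveCSM(gen$structure, "c3", cfg)
  r2 <- solveCSM(gen$structure, "c3", cfg)
  expect_identical(csmValue(r1), csmValue(r2))
  expect_identical(symmetryAxis(r1), symmetryAxis(r2))
  expect_identical(atomPermutation(r1), atomPermutation(r2))
})

test_that("S is invariant under rigid motion and uniform scaling", {
  gen <- syntheticHomomer(3, 6, noiseSigma = 0.05, seed = 41)
  st <- gen$structure
  cfg <- csmConfig(restarts = 2L)
  s0 <- csmValue(solveCSM(st, "c3", cfg))
  set.seed(4)
  th <- runif(3, 0, 2 * pi)
  R <- quatsym:::rotationMatrix(c(0, 0, 1), th[1]) %*%
       quatsym:::rotationMatrix(c(0, 1, 0), th[2]) %*%
       quatsym:::rotationMatrix(c(1, 0, 0), th[3])
  moved <- transformStructure(st, rotation = R, translation = c(30, -12, 5))
  expect_equal(csmValue(solveCSM(moved, "c3", cfg)), s0, tolerance = 1e-9)
  scaled <- transformStructure(st, scale = 2.7)
  expect_equal(csmValue(solveCSM(scaled, "c3", cfg)), s0, tolerance = 1e-9)
})

test_that("hungarian never loses to sequence-ordered, and wins on swapped branches", {
  winners <- 0L
  total <- 8L
  for (s in seq_len(total)) {
    gen <- syntheticHomomer(2, 6, noiseSigma = 0.2, seed = 100 + s,
                            swapBranchLabels = TRUE)
    sh <- csmValue(solveCSM(gen$structure, "c2", csmConfig(strategy = "hungarian", restarts = 2L)))
    ss <- csmValue(solveCSM(gen$structure, "c2", csmConfig(strategy = "sequence", restarts = 2L)))
    expect_lte(sh, ss + 1e-12)
    if (sh < ss - 1e-12) winners <- winners + 1L
  }
  expect_gte(winners, ceiling(0.95 * total))
})

test_that("flat per-class assignment can mix peptides; many-chains cannot", {
  gen <- syntheticHomomer(3, 6, noiseSigma = 0.5, seed = 77)
  st <- gen$structure
  res <- solveCSM(st, "c3", csmConfig(manyChains = FALSE, restarts = 2L))
  expect_s4_class(res, "CSMResult")
  expect_length(peptidePermutation(res), 0)
  resMC <- solveCSM(st, "c3", csmConfig(restarts = 2L))
  peps <- peptideIndices(st)
  pepOf <- integer(nAtoms(st))
  for (p in seq_along(peps)) pepOf[peps[[p]]] <- p
  pp <- peptidePermutation(resMC)
  for (i in seq_along(peps))
    expect_true(all(pepOf[atomPermutation(resMC)[peps[[i]]]] == pp[i]))
})

test_that("chirality: achiral dimer scores zero, chiral perturbation does not", {
  gen <- syntheticHomomer(2, 6, group = pointGroup("S", 1), noiseSigma = 0,
                          seed = 9)
  cfg <- csmConfig(restarts = 3L)
  ccm0 <- csmValue(solveChirality(gen$structure, cfg))
  expect_lte(ccm0, 1e-9)
  # shear the z coordinates of one chain to break achirality
  st <- gen$structure
  bIdx <- peptideIndices(st)[["B"]]
  st@atoms$z[bIdx] <- st@atoms$z[bIdx] + 0.3 * st@atoms$x[bIdx]
  ccm1 <- csmValue(solveChirality(st, cfg))
  expect_gt(ccm1, 1e-4)
  # parity: the CCM of the mirror image is the same
  ccm1m <- csmValue(solveChirality(reflectStructure(st), cfg))
  expect_equal(ccm1m, ccm1, tolerance = 1e-9)
})

test_that("solver rejects single-peptide structures", {
  gen <- syntheticHomomer(2, 4, noiseSigma = 0, seed = 1)
  st <- gen$structure
  st@atoms <- st@atoms[st@atoms$chainId == "A", ]
  expect_error(solveCSM(st, "c2"), "out of scope")
})

test_that("subgroup nesting: S(C2) <= S(C6) on noisy hexamers", {
  gen <- syntheticHomomer(6, 4, noiseSigma = 0.3, seed = 61)
  cfg <- csmConfig(restarts = 2L)
  s2 <- csmValue(solveCSM(gen$structure, "c2", cfg))
  s6 <- csmValue(solveCSM(gen$structure, "c6", cfg))
  expect_lte(s2, s6 + 1e-9)
})
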