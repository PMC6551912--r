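test_that("generator matrices are orthogonal with the right determinant and order", {
  for (spec in list(list("C", 2L), list("C", 5L), list("S", 1L),
                    list("S", 2L), list("S", 4L))) {
    grp <- pointGroup(spec[[1]], spec[[2]])
    op <- symmetryOperation(grp, c(1, 2, 2) / 3, c(0, 0, 0))
    M <- quatsym:::generatorMatrix(op)
    expect_equal(crossprod(M), diag(3), tolerance = 1e-12)
    expect_equal(det(M), if (spec[[1]] == "S") -1 else 1, tolerance = 1e-12)
    n <- operationOrder(grp)
    expect_equal(quatsym:::operationMatrix(op, n), diag(3), tolerance = 1e-10)
  }
})

test_that("closed-form actions: C2 rotation, inversion, T^n identity on points", {
  opC2 <- symmetryOperation(pointGroup("C", 2), c(0, 0, 1))
  expect_equal(drop(applyOperation(opC2, matrix(c(1, 0, 0), 1))),
               c(-1, 0, 0), tolerance = 1e-12)
  opS2 <- symmetryOperation(pointGroup("S", 2), c(0, 0, 1))
  expect_equal(drop(applyOperation(opS2, matrix(c(1, 2, 3), 1))),
               c(-1, -2, -3), tolerance = 1e-12)
  opC5 <- symmetryOperation(pointGroup("C", 5), c(1, 1, 1) / sqrt(3),
                            origin = c(2, -1, 4))
  pts <- matrix(rnorm(15), ncol = 3)
  expect_equal(applyOperation(opC5, pts, 5L), pts, tolerance = 1e-10)
})

test_that("group labels parse and odd Sn beyond the chirality targets is rejected", {
  expect_equal(parseGroup("c5")@n, 5L)
  expect_equal(parseGroup("S2")@kind, "S")
  expect_error(parseGroup("q3"), "parse")
  expect_error(pointGroup("S", 3), "odd")
  expect_equal(operationOrder(pointGroup("S", 1)), 2L)
  expect_equal(operationOrder(pointGroup("C", 6)), 6L)
})

test_that("evaluateCSM equals direct term-by-term summation on a planar toy", {
  # 4 points, hand-chosen axis and permutation, C2
  xyz <- rbind(c(2, 0, 0), c(0, 1.5, 0), c(-1.8, 0, 0.3), c(0, -1, -0.2))
  st <- pointStructure(xyz, chainId = c("A", "A", "B", "B"),
                       resSeq = c(1, 2, 1, 2))
  grp <- pointGroup("C", 2)
  axis <- unname(c(1, 1, 4) / sqrt(18))
  op <- symmetryOperation(grp, axis, centroid(st))
  perm <- c(3L, 4L, 1L, 2L)
  res <- evaluateCSM(st, op, perm)
  mDirect <- directOrbitObjective(st, grp, perm, axis) / (2 * 2)
  nDirect <- sum(sweep(xyz, 2, colMeans(xyz))^2)
  expect_equal(res@mValue, mDirect, tolerance = 1e-12)
  expect_equal(res@normValue, nDirect, tolerance = 1e-12)
  expect_equal(csmValue(res), 100 * mDirect / nDirect, tolerance = 1e-12)
})

test_that("an exact Cn orbit scores zero with the true axis and orbit permutation", {
  for (n in c(2L, 5L)) {
    gen <- syntheticHomomer(n, 4, noiseSigma = 0, seed = n)
    st <- gen$structure
    part <- buildPartition(st)
    op <- symmetryOperation(pointGroup("C", n), gen$groundTruth$axis,
                            centroid(st))
    tl <- sequenceOrderedAssign(st, part, gen$groundTruth$orbitPerm)
    expect_lte(csmValue(evaluateCSM(st, op, tl@global)), 1e-10)
  }
})

test_that("coincident atoms make the CSM undefined", {
  st <- pointStructure(matrix(1, 4, 3))
  op <- symmetryOperation(pointGroup("C", 2), c(0, 0, 1), c(1, 1, 1))
  expect_error(evaluateCSM(st, op, c(2L, 1L, 4L, 3L)), "N\\(G\\) = 0")
})

test_that("nearest structure: fixed point, two-atom average, and orbit identities", {
  # perfectly symmetric input is a fixed point of orbit averaging
  gen <- syntheticHomomer(3, 4, noiseSigma = 0, seed = 3)
  st <- gen$structure
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 3), gen$groundTruth$axis, centroid(st))
  tl <- sequenceOrderedAssign(st, part, gen$groundTruth$orbitPerm)
  P <- nearestStructure(st, op, tl@global)
  expect_equal(P, coords(st), tolerance = 1e-9, ignore_attr = TRUE)

  # hand-computed 2-point C2 average: each P_k = (Q_k + T^-1 Q_pi(k)) / 2
  xyz <- rbind(c(1, 0, 0), c(-1, 0, 0.4))
  st2 <- pointStructure(xyz, chainId = c("A", "B"), resSeq = c(1, 1))
  op2 <- symmetryOperation(pointGroup("C", 2), c(0, 0, 1),
                           origin = c(0, 0, 0))
  P2 <- nearestStructure(st2, op2, c(2L, 1L))
  expect_equal(P2, rbind(c(1, 0, 0.2), c(-1, 0, 0.2)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # noisy orbit: T P_k = P_pi(k), and the displacement to P reproduces M(G)
  gen <- syntheticHomomer(4, 6, noiseSigma = 0.3, seed = 12)
  st <- gen$structure
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 4), gen$groundTruth$axis, centroid(st))
  tl <- manyChainsAssign(st, part, op, "hungarian")
  cyc <- validateCycleStructure(tl@global, pointGroup("C", 4))
  expect_true(cyc$valid)
  res <- evaluateCSM(st, op, tl@global)
  P <- nearestCoords(res)
  TP <- applyOperation(op, P, 1L)
  expect_lt(max(abs(TP - P[tl@global, ])), 1e-9)
  expect_equal(sum((coords(st) - P)^2), res@mValue,
               tolerance = 1e-9)
})

test_that("optimalAxis recovers a planted exact axis and beats its init", {
  gen <- syntheticHomomer(3, 5, noiseSigma = 0, seed = 6,
                          axis = c(1, -2, 2) / 3)
  st <- gen$structure
  part <- buildPartition(st)
  tl <- sequenceOrderedAssign(st, part, gen$groundTruth$orbitPerm)
  op <- optimalAxis(st, pointGroup("C", 3), tl@global, init = c(0, 0, 1))
  expect_lt(angleToAxis(op@axis, gen$groundTruth$axis), 1e-6)
  expect_lte(attr(op, "objective"),
             orbitObjectiveFast(st, pointGroup("C", 3), tl@global, c(0, 0, 1)))
})

test_that("optimalAxis matches a dense grid-search oracle on random problems", {
  set.seed(31)
  for (t in 1:6) {
    N <- sample(6:12, 1)
    st <- pointStructure(matrix(rnorm(3 * N, sd = 3), ncol = 3))
    grp <- pointGroup("C", sample(2:4, 1))
    perm <- sample(N)
    fOpt <- attr(optimalAxis(st, grp, perm), "objective")
    fGrid <- gridAxisOracle(st, grp, perm, stepDeg = 4)
    expect_lt(abs(fOpt - fGrid), 1e-8 * (1 + abs(fGrid)))
  }
})

test_that("inversion leaves the axis undetermined and flags degeneracy", {
  gen <- syntheticHomomer(2, 4, noiseSigma = 0.1, seed = 2)
  st <- gen$structure
  part <- buildPartition(st)
  tl <- sequenceOrderedAssign(st, part, c(2L, 1L))
  op <- optimalAxis(st, pointGroup("S", 2), tl@global, init = c(0, 1, 0))
  expect_true(attr(op, "degenerate"))
  # objective truly axis-independent
  f1 <- orbitObjectiveFast(st, pointGroup("S", 2), tl@global, c(0, 0, 1))
  f2 <- orbitObjectiveFast(st, pointGroup("S", 2), tl@global,
                           c(2, -1, 1) / sqrt(6))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("cycle-structure validation distinguishes legal and illegal cycles", {
  g4 <- pointGroup("C", 4)
  expect_true(validateCycleStructure(c(2L, 3L, 4L, 1L), g4)$valid)  # 4-cycle
  expect_true(validateCycleStructure(1:4, g4)$valid)                # fixed points
  bad <- validateCycleStructure(c(2L, 1L, 4L, 3L), g4)              # 2-cycles
  expect_false(bad$valid)
  expect_true(validateCycleStructure(c(2L, 1L, 4L, 3L),
                                     pointGroup("C", 2))$valid)
})
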