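test_that("hungarianAssign solves the 2x2 worked example and zero-diagonal cases", {
  A <- rbind(c(0, 1), c(0.5, 10))
  mu <- hungarianAssign(A)
  expect_equal(as.integer(mu), c(2L, 1L))
  expect_equal(attr(mu, "cost"), 1.5)
  B <- matrix(5, 4, 4) - diag(5, 4)
  muB <- hungarianAssign(B)
  expect_equal(as.integer(muB), 1:4)
  expect_equal(attr(muB, "cost"), 0)
  expect_error(hungarianAssign(matrix(1, 2, 3)), "square")
  expect_error(hungarianAssign(matrix(c(1, Inf, 2, 3), 2)), "finite")
})

test_that("hungarianAssign equals exhaustive search on random matrices up to 7x7", {
  set.seed(101)
  for (t in 1:60) {
    k <- sample(2:7, 1)
    A <- matrix(stats::runif(k * k), k)
    mu <- hungarianAssign(A)
    oracle <- bruteAssign(A)
    expect_equal(attr(mu, "cost"), oracle$cost, tolerance = 1e-12)
  }
})

test_that("greedy follows the smallest-remaining-entry rule and is never better", {
  A <- rbind(c(0, 1), c(0.5, 10))
  mu <- greedyAssign(A)                 # picks A11 = 0 first, forced A22
  expect_equal(as.integer(mu), c(1L, 2L))
  expect_equal(attr(mu, "cost"), 10)
  expect_gt(attr(mu, "cost"), attr(hungarianAssign(A), "cost"))
  B <- matrix(5, 3, 3) - diag(5, 3)
  expect_equal(as.integer(greedyAssign(B)), 1:3)
  set.seed(55)
  for (t in 1:40) {
    k <- sample(2:8, 1)
    M <- matrix(stats::runif(k * k), k)
    expect_gte(attr(greedyAssign(M), "cost"),
               attr(hungarianAssign(M), "cost") - 1e-12)
  }
})

test_that("sequence-ordered assignment maps equal ordinals across peptides", {
  gen <- syntheticHomomer(2, 5, noiseSigma = 0.1, seed = 21)
  st <- gen$structure
  part <- buildPartition(st)
  tl <- sequenceOrderedAssign(st, part, c(2L, 1L))
  peps <- peptideIndices(st)
  M <- length(peps[[1]])
  expect_equal(tl@global[peps[[1]]], peps[[2]])
  expect_equal(tl@global[peps[[2]]], peps[[1]])
  expect_equal(tl@global[peps[[1]][3]], peps[[2]][3])
})

test_that("many-chains picks A -> B on a homodimer and never mixes peptides", {
  gen <- syntheticHomomer(2, 6, noiseSigma = 0.2, seed = 3)
  st <- gen$structure
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 2), gen$groundTruth$axis, centroid(st))
  tl <- manyChainsAssign(st, part, op, "hungarian")
  expect_equal(tl@peptidePerm, c(2L, 1L))
  expect_equal(peptideCycleNotation(st, tl), "A -> B")
  peps <- peptideIndices(st)
  pepOf <- integer(nAtoms(st))
  for (p in seq_along(peps)) pepOf[peps[[p]]] <- p
  for (i in seq_along(peps))
    expect_true(all(pepOf[tl@global[peps[[i]]]] == tl@peptidePerm[i]))
  # class preservation: pi never changes residue number or type
  at <- atomTable(st)
  expect_equal(at$resSeq[tl@global], at$resSeq)
  expect_equal(at$resName[tl@global], at$resName)
  expect_equal(at$element[tl@global], at$element)
})

test_that("many-chains recovers a planted cyclic order from scrambled file order", {
  gen <- syntheticHomomer(4, 6, noiseSigma = 0.05, seed = 17,
                          scrambleChainOrder = TRUE)
  st <- gen$structure
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 4), gen$groundTruth$axis, centroid(st))
  tl <- manyChainsAssign(st, part, op, "hungarian")
  expect_true(sameOrbit(tl@peptidePerm, gen$groundTruth$orbitPerm))
  expect_false(identical(tl@peptidePerm, c(2L, 3L, 4L, 1L)))  # not file order
})

test_that("per-class costs order hungarian <= greedy and hungarian <= sequence", {
  gen <- syntheticHomomer(3, 8, noiseSigma = 0.4, seed = 23,
                          swapBranchLabels = TRUE)
  st <- gen$structure
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 3), gen$groundTruth$axis, centroid(st))
  th <- manyChainsAssign(st, part, op, "hungarian")
  tg <- manyChainsAssign(st, part, op, "greedy")
  perm <- th@peptidePerm
  costOf <- function(tl) sum(tl@pairCosts[cbind(seq_along(perm), perm)])
  ts <- sequenceOrderedAssign(st, part, perm)
  Q <- coords(st)
  TQ <- applyOperation(op, Q, 1L)
  seqCost <- sum((TQ - Q[ts@global, ])^2)
  expect_lte(costOf(th), costOf(tg) + 1e-12)
  expect_lte(costOf(th), seqCost + 1e-12)
})

test_that("pair costs depend on geometry, not within-class atom order", {
  gen <- syntheticHomomer(2, 6, noiseSigma = 0.3, seed = 29,
                          swapBranchLabels = TRUE)
  st <- gen$structure
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 2), gen$groundTruth$axis, centroid(st))
  B1 <- manyChainsAssign(st, part, op, "hungarian")@pairCosts
  # reorder the atoms inside each Val CG1/CG2 class (same swap in every
  # chain, so the prepared invariant is kept but class-internal order flips)
  at <- atomTable(st)
  swap <- st
  for (ch in chainIds(st))
    for (r in unique(at$resSeq[at$resName == "VAL" & at$chainId == ch])) {
      ia <- which(at$chainId == ch & at$resSeq == r & at$name == "CG1")
      ib <- which(at$chainId == ch & at$resSeq == r & at$name == "CG2")
      swap@atoms[c(ia, ib), ] <- swap@atoms[c(ib, ia), ]
    }
  part2 <- buildPartition(swap)
  B2 <- manyChainsAssign(swap, part2, op, "hungarian")@pairCosts
  expect_equal(B1, B2, tolerance = 1e-10)
})

test_that("single-peptide input yields identity with a warning", {
  gen <- syntheticHomomer(2, 4, noiseSigma = 0, seed = 1)
  st <- gen$structure
  st@atoms <- st@atoms[st@atoms$chainId == "A", ]
  part <- buildPartition(st)
  op <- symmetryOperation(pointGroup("C", 2), c(0, 0, 1), centroid(st))
  expect_warning(tl <- manyChainsAssign(st, part, op, "hungarian"),
                 "single peptide")
  expect_equal(tl@global, seq_len(nAtoms(st)))
})
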