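# Shared fixtures and independent oracles for the test suite.

# -- tiny hand-written PDB text ---------------------------------------------

dimerPDBLines <- function() {
  c("REMARK 465 MISSING RESIDUES",
    "REMARK 465   M RES C SSSEQI",
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  N  BGLY A   1       0.500   0.000   0.000  1.00  0.00           N",
    "ATOM      3  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  HA  GLY A   1       1.200   0.000   0.000  1.00  0.00           H",
    "ATOM      5  N   ALA A   2       2.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
    "TER",
    "ATOM      7  N   GLY B   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      8  CA  GLY B   1       1.000   1.000   0.000  1.00  0.00           C",
    "ATOM      9  CA  ALA B   2       3.000   1.000   0.000  1.00  0.00           C",
    "ATOM     10  O   HOH B  99       9.000   9.000   9.000  1.00  0.00           O",
    "END")
}

writeTempPDB <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# a minimal single-atom-per-residue structure from raw coordinates
pointStructure <- function(xyz, chainId = "A", resSeq = seq_len(nrow(xyz))) {
  n <- nrow(xyz)
  if (length(chainId) == 1L) chainId <- rep(chainId, n)
  new("ProteinStructure",
      atoms = data.frame(record = "ATOM", serial = seq_len(n), name = "CA",
                         altLoc = "", resName = "GLY", chainId = chainId,
                         resSeq = resSeq, iCode = "",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         occupancy = 1, tempFactor = 0, element = "C",
                         stringsAsFactors = FALSE),
      sourceId = "test")
}

# -- independent oracles ----------------------------------------------------

# all permutations of 1..n (recursive enumeration)
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in allPerms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# memoised permutation matrices for the fast exhaustive oracle
.permCache <- new.env(parent = emptyenv())
allPermsMatrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  m <- do.call(rbind, lapply(allPerms(n), as.integer))
  .permCache[[key]] <- m
  m
}

# vectorised exhaustive-search assignment minimum (cost only)
bruteAssignCost <- function(cost) {
  k <- nrow(cost)
  pm <- allPermsMatrix(k)
  lin <- sweep((pm - 1L) * k, 2, seq_len(k), "+")
  # flatten: a 2-column index matrix would otherwise be read as (row, col)
  min(rowSums(matrix(cost[as.integer(lin)], nrow = nrow(pm))))
}

# exhaustive-search assignment minimum
bruteAssign <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  bestMu <- NULL
  for (mu in allPerms(n)) {
    cst <- sum(cost[cbind(seq_len(n), mu)])
    if (cst < best) {
      best <- cst
      bestMu <- mu
    }
  }
  list(mu = bestMu, cost = best)
}

# direct term-by-term orbit objective (independent of optimalAxis's
# quadratic-form algebra): explicit generator matrices and plain sums
directOrbitObjective <- function(structure, group, perm, axis) {
  op <- symmetryOperation(group, axis, centroid(structure))
  n <- operationOrder(group)
  Q <- coords(structure)
  s <- 0
  pk <- seq_len(nrow(Q))
  for (i in seq_len(n)) {
    pk <- perm[pk]
    TQ <- applyOperation(op, Q, i)
    for (k in seq_len(nrow(Q)))
      s <- s + sum((TQ[k, ] - Q[pk[k], ])^2)
  }
  s
}

# fast self-contained variant for the grid oracle: Rodrigues rotation
# and plain sums, no package geometry code involved
orbitObjectiveFast <- function(structure, group, perm, axis) {
  n <- operationOrder(group)
  improper <- group@kind == "S"
  theta <- 2 * pi / group@n
  Qc <- sweep(coords(structure), 2, colMeans(coords(structure)))
  v <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  G <- diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * tcrossprod(v)
  if (improper) G <- (diag(3) - 2 * tcrossprod(v)) %*% G
  s <- 0
  pk <- seq_len(nrow(Qc))
  Mi <- diag(3)
  for (i in seq_len(n)) {
    pk <- perm[pk]
    Mi <- G %*% Mi
    s <- s + sum((Qc %*% t(Mi) - Qc[pk, , drop = FALSE])^2)
  }
  s
}

# dense full-sphere grid search plus two-stage local refinement
gridAxisOracle <- function(structure, group, perm, stepDeg = 2) {
  best <- Inf
  bp <- c(0, 0)
  for (th in seq(0, 180, by = stepDeg) * pi / 180) {
    for (ph in seq(0, 360 - stepDeg, by = stepDeg) * pi / 180) {
      v <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      f <- orbitObjectiveFast(structure, group, perm, v)
      if (f < best) {
        best <- f
        bp <- c(th, ph)
      }
    }
  }
  fo <- function(p) orbitObjectiveFast(structure, group, perm,
                                       c(sin(p[1]) * cos(p[2]),
                                         sin(p[1]) * sin(p[2]), cos(p[1])))
  o <- stats::optim(bp, fo, control = list(reltol = 1e-16, maxit = 5000))
  o <- stats::optim(o$par, fo, method = "BFGS", control = list(maxit = 1000))
  min(best, o$value)
}

angleToAxis <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

# cyclic-order comparison: recovered peptide orbit equals the planted
# one traversed in either direction
sameOrbit <- function(perm, planted) {
  identical(as.integer(perm), as.integer(planted)) ||
    identical(order(perm), as.integer(planted)) ||
    {
      inv <- integer(length(planted))
      inv[planted] <- seq_along(planted)
      identical(as.integer(perm), inv)
    }
}
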