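# Symmetry operations and the CSM objective.
#
# For a cyclic group G generated by T (proper or improper rotation by
# 360/n degrees about a unit axis v through the centroid Q0):
#   S(G)  = 100 * M(G) / N(G)
#   N(G)  = sum_k |Q_k - Q0|^2
#   M(G)  = (1/2n) min sum_{i=1..n} sum_k |T^i Q_k - Q_{pi^i(k)}|^2
# and the nearest G-symmetric structure is the orbit average
#   P_k = (1/n) sum_{i=1..n} T^{-i} Q_{pi^i(k)}.

#' Construct a cyclic point group
#'
#' @param kind "C" (proper rotation) or "S" (improper rotation;
#'   rotation composed with reflection through the perpendicular plane).
#' @param n group index; the generator rotates by 360/n degrees. For
#'   "S", n = 1 is the mirror group and n = 2 the inversion group (the
#'   chirality targets); larger n must be even.
#' @return a [PointGroup-class].
#' @examples
#' pointGroup("C", 5)
#' pointGroup("S", 2)  # inversion
#' @export
pointGroup <- function(kind = c("C", "S"), n) {
  kind <- toupper(match.arg(kind))
  new("PointGroup", kind = kind, n = as.integer(n))
}

#' Parse a group label such as "c5" or "S2"
#'
#' @param label character like "C3", "c2", "s1".
#' @return a [PointGroup-class].
#' @export
parseGroup <- function(label) {
  m <- regmatches(label, regexec("^([CcSs])([0-9]+)$", label))[[1]]
  if (length(m) != 3)
    stop("cannot parse point-group label '", label, "' (expected e.g. c2, C5, s2)")
  pointGroup(toupper(m[2]), as.integer(m[3]))
}

#' Number of group elements summed over in the CSM formulas
#'
#' For Cn and even Sn this equals n; for the chirality targets S1
#' (mirror) and S2 (inversion) the generated group has two elements, so
#' the orbit sums run over i = 1, 2 and T^2 = identity.
#'
#' @param group a [PointGroup-class].
#' @return integer.
#' @export
operationOrder <- function(group) {
  if (group@kind == "C") return(group@n)
  if (group@n <= 2L) 2L else group@n
}

#' Construct a symmetry operation
#'
#' @param group a [PointGroup-class] (or label string).
#' @param axis direction of the symmetry axis (normalised internally).
#' @param origin point the axis passes through (default origin).
#' @return a [SymmetryOperation-class].
#' @export
symmetryOperation <- function(group, axis, origin = c(0, 0, 0)) {
  if (is.character(group)) group <- parseGroup(group)
  new("SymmetryOperation", group = group, axis = unitVector(axis),
      origin = as.numeric(origin))
}

# Rotation by `angle` about unit vector v (Rodrigues).
rotationMatrix <- function(v, angle) {
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(v)
}

# The generator matrix of the operation: rotation by 360/n degrees,
# composed with reflection through the plane perpendicular to the axis
# for improper groups.
generatorMatrix <- function(op) {
  n <- op@group@n
  R <- rotationMatrix(op@axis, 2 * pi / n)
  if (op@group@kind == "S") R <- (diag(3) - 2 * tcrossprod(op@axis)) %*% R
  R
}

# T^i as a 3x3 matrix (matrix power of the single generator, so the
# rotation-reflection alternation of Sn falls out automatically).
operationMatrix <- function(op, power = 1L) {
  if (power == 0L) return(diag(3))
  G <- generatorMatrix(op)
  M <- G
  for (i in seq_len(power - 1L)) M <- G %*% M
  M
}

#' Apply a power of a symmetry operation to coordinates
#'
#' Translates by minus the origin, applies the i-th power of the
#' generator T, and translates back.
#'
#' @param op a [SymmetryOperation-class].
#' @param xyz numeric N x 3 coordinate matrix.
#' @param power integer i >= 0.
#' @return transformed N x 3 matrix.
#' @export
applyOperation <- function(op, xyz, power = 1L) {
  xyz <- as.matrix(xyz)
  M <- operationMatrix(op, power)
  sweep(sweep(xyz, 2, op@origin) %*% t(M), 2, op@origin, "+")
}

#' Validate the cycle structure of a permutation
#'
#' For pi induced by a genuine T-invariant structure, cycles can only
#' have length 1, 2 or n (2 only for Sn or C2). The assignment solver
#' deliberately does not enforce this; this validator reports
#' violations after the fact.
#'
#' @param perm integer permutation.
#' @param group a [PointGroup-class].
#' @return list(valid = logical, badCycles = list of offending cycles).
#' @export
validateCycleStructure <- function(perm, group) {
  n <- operationOrder(group)
  allow2 <- group@kind == "S" || (group@kind == "C" && group@n == 2L)
  lens <- lengths(permCycles(perm))
  ok <- lens == 1L | lens == n | (allow2 & lens == 2L)
  list(valid = all(ok),
       badCycles = permCycles(perm)[!ok])
}

#' Nearest G-symmetric structure for a fixed operation and permutation
#'
#' Orbit averaging: P_k = (1/n) sum_i T^{-i} Q_{pi^i(k)}. When pi has a
#' valid cycle structure the result is exactly T-invariant as a set:
#' T P_k = P_{pi(k)}.
#'
#' @param structure a [ProteinStructure-class].
#' @param op a [SymmetryOperation-class].
#' @param perm integer atom permutation pi.
#' @return N x 3 matrix of nearest-symmetric coordinates.
#' @export
nearestStructure <- function(structure, op, perm) {
  Q <- coords(structure)
  n <- operationOrder(op@group)
  P <- matrix(0, nrow(Q), 3)
  pk <- seq_len(nrow(Q))
  for (i in seq_len(n)) {
    pk <- perm[pk]                        # pi^i
    P <- P + applyOperation(op, Q[pk, , drop = FALSE], n - i)  # T^{-i} = T^{n-i}
  }
  P / n
}

#' Evaluate the CSM for a fixed operation and permutation
#'
#' Computes M(G) by the permutation-form double sum with its 1/(2n)
#' prefactor, N(G) as the coordinate spread about the centroid, S(G) =
#' 100 M/N, and the nearest symmetric structure.
#'
#' @param structure a [ProteinStructure-class].
#' @param op a [SymmetryOperation-class]; its origin should be the
#'   structure centroid (use [symmetryOperation()] with
#'   `origin = centroid(structure)`).
#' @param perm integer atom permutation pi of 1..N.
#' @param strategy label recorded on the result (bookkeeping only).
#' @return a [CSMResult-class].
#' @export
evaluateCSM <- function(structure, op, perm, strategy = "fixed") {
  Q <- coords(structure)
  N <- nrow(Q)
  if (length(perm) != N || anyDuplicated(perm) || !setequal(perm, seq_len(N)))
    stop("perm must be a permutation of 1..N")
  ctr <- centroid(structure)
  norm <- sum(sweep(Q, 2, ctr)^2)
  if (norm <= 0) stop("all atoms coincide: N(G) = 0, the CSM is undefined")
  n <- operationOrder(op@group)
  m <- 0
  pk <- seq_len(N)
  for (i in seq_len(n)) {
    pk <- perm[pk]
    m <- m + sum((applyOperation(op, Q, i) - Q[pk, , drop = FALSE])^2)
  }
  m <- m / (2 * n)
  new("CSMResult", sValue = 100 * m / norm, mValue = m, normValue = norm,
      operation = op, permutation = as.integer(perm),
      peptidePerm = integer(0),
      nearest = nearestStructure(structure, op, perm),
      iterations = 0L, converged = TRUE, degenerate = FALSE,
      strategy = strategy)
}

# ---- optimal axis for a fixed permutation --------------------------------
#
# Expanding sum_i sum_k |T^i Q_k - Q_{pi^i(k)}|^2 with Rodrigues' formula,
# the objective is  const - 2 g(v)  with
#   g(v) = sum_i [ cos(phi_i) P_i + sin(phi_i) <v, c_i> + w_i v' M_i v ]
# where phi_i = i * 2pi/n, a_k = Q_k, b_k = Q_{pi^i(k)},
#   P_i = sum_k <a_k, b_k>,  c_i = sum_k a_k x b_k,
#   M_i = sym(sum_k a_k b_k'),
#   w_i = 1 - cos(phi_i)        for proper powers,
#   w_i = -(1 + cos(phi_i))     for improper powers (odd i of Sn).
# Maximising g(v) = v'Av + d'v on the unit sphere is the classical
# sphere-constrained quadratic problem, solved through the eigenbasis of
# A and the secular equation of its Lagrange condition.

axisObjectiveParts <- function(Q, perm, group) {
  n <- operationOrder(group)
  improper <- group@kind == "S"
  theta <- 2 * pi / group@n
  A <- matrix(0, 3, 3)
  d <- c(0, 0, 0)
  const <- 0
  pk <- seq_len(nrow(Q))
  for (i in seq_len(n)) {
    pk <- perm[pk]
    B <- Q[pk, , drop = FALSE]
    phi <- i * theta
    Mi <- crossprod(Q, B)                # sum a b'
    Pi <- sum(diag(Mi))
    ci <- c(sum(Q[, 2] * B[, 3] - Q[, 3] * B[, 2]),
            sum(Q[, 3] * B[, 1] - Q[, 1] * B[, 3]),
            sum(Q[, 1] * B[, 2] - Q[, 2] * B[, 1]))
    wi <- if (improper && i %% 2L == 1L) -(1 + cos(phi)) else (1 - cos(phi))
    A <- A + wi * (Mi + t(Mi)) / 2
    d <- d + sin(phi) * ci
    const <- const + sum(Q^2) + sum(B^2) - 2 * cos(phi) * Pi
  }
  list(A = A, d = d, const = const)
}

# Maximise v'Av + d'v over the unit sphere. Returns the maximiser and a
# degeneracy flag (TRUE when the objective does not determine the axis).
maximizeQuadOnSphere <- function(A, d, fallback = c(0, 0, 1)) {
  e <- eigen(A, symmetric = TRUE)
  al <- e$values
  U <- e$vectors
  scale <- max(abs(al), vecNorm(d), 1e-12)
  dt <- drop(crossprod(U, d)) / 2
  if (vecNorm(d) < 1e-11 * scale) {
    if (al[1] - al[3] < 1e-11 * scale)
      return(list(v = unitVector(fallback), degenerate = TRUE))
    # sign-free: the objective is even in v here
    v <- canonicalAxis(unitVector(U[, 1]))
    return(list(v = v, degenerate = (al[1] - al[2]) < 1e-11 * scale))
  }
  amax <- al[1]
  phi <- function(lam) sum((dt / (lam - al))^2)
  topTol <- 1e-10 * scale
  top <- which(al > amax - topTol)
  hard <- all(abs(dt[top]) < 1e-12 * scale)
  if (hard) {
    rest <- setdiff(1:3, top)
    w <- numeric(3)
    w[rest] <- dt[rest] / (amax - al[rest])
    nw <- sum(w^2)
    if (nw <= 1) {
      w[top[1]] <- sqrt(max(0, 1 - nw))
      v <- drop(U %*% w)
      return(list(v = unitVector(v), degenerate = FALSE))
    }
    # fall through: a root exists strictly above amax using rest components
  }
  lo <- amax + max(1e-14 * scale, 1e-300)
  hi <- amax + vecNorm(d) / 2 + scale * 1e-9 + 1
  while (phi(lo) < 1 && lo > amax) lo <- amax + (lo - amax) / 8
  f <- function(lam) phi(lam) - 1
  lam <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-14 * (1 + abs(amax)),
                                 maxiter = 2000)$root,
                  error = function(e) hi)
  v <- drop(U %*% (dt / (lam - al)))
  list(v = unitVector(v), degenerate = FALSE)
}

#' Optimal symmetry axis for a fixed permutation
#'
#' For a fixed atom permutation pi the full orbit objective is a
#' quadratic form in the axis direction; the constrained optimum over
#' the unit sphere is found in closed form through the eigenbasis of the
#' quadratic part (secular-equation solution of the Lagrange condition).
#' If the objective cannot beat the value at `init` (within numerical
#' noise), `init` is returned, so the contract "returned objective <=
#' objective at init" always holds.
#'
#' @param structure a [ProteinStructure-class].
#' @param group a [PointGroup-class].
#' @param perm integer atom permutation.
#' @param init initial/reference axis direction.
#' @return a [SymmetryOperation-class] with attributes `degenerate`
#'   (logical) and `objective` (the achieved orbit-sum value).
#' @export
optimalAxis <- function(structure, group, perm, init = c(0, 0, 1)) {
  ctr <- centroid(structure)
  Q <- sweep(coords(structure), 2, ctr)
  parts <- axisObjectiveParts(Q, perm, group)
  sol <- maximizeQuadOnSphere(parts$A, parts$d, fallback = unitVector(init))
  objAt <- function(v) {
    op <- symmetryOperation(group, v, ctr)
    n <- operationOrder(group)
    s <- 0
    pk <- seq_len(nrow(Q))
    Q0 <- coords(structure)
    for (i in seq_len(n)) {
      pk <- perm[pk]
      s <- s + sum((applyOperation(op, Q0, i) - Q0[pk, , drop = FALSE])^2)
    }
    s
  }
  vBest <- sol$v
  fBest <- objAt(vBest)
  fInit <- objAt(unitVector(init))
  if (fInit < fBest - 1e-12 * (1 + abs(fBest))) {
    vBest <- unitVector(init)
    fBest <- fInit
  }
  op <- symmetryOperation(group, vBest, ctr)
  attr(op, "degenerate") <- sol$degenerate
  attr(op, "objective") <- fBest
  op
}
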