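# Iterative approximate CSM solver: alternate between computing the
# class-preserving permutation from the current axis and the optimal
# axis from the current permutation, from a centroid-regression initial
# guess plus seeded restarts; keep the best state seen.

#' Solver configuration
#'
#' @param maxIterations maximum alternating iterations per start
#'   (default 50; well-formed homomers typically converge in 2-4).
#' @param axisTolerance radians; stop when successive axes (as lines)
#'   differ by less (default 1e-6).
#' @param csmTolerance stop when successive S values differ by less
#'   (default 1e-10).
#' @param restarts total number of starts: the centroid-regression guess
#'   plus seeded perturbed and random directions (default 8).
#' @param seed integer seed for the restart directions (default 1).
#' @param strategy atom-level assignment strategy: "hungarian",
#'   "greedy" or "sequence".
#' @param manyChains logical; use the two-level peptide-preserving
#'   assignment (default TRUE). When FALSE the flat per-class scheme is
#'   used ("sequence" requires manyChains).
#' @return a list of class "csmConfig".
#' @export
csmConfig <- function(maxIterations = 50L, axisTolerance = 1e-6,
                      csmTolerance = 1e-10, restarts = 8L, seed = 1L,
                      strategy = c("hungarian", "greedy", "sequence"),
                      manyChains = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(maxIterations >= 1L, axisTolerance > 0, csmTolerance > 0,
            restarts >= 1L)
  if (!manyChains && strategy == "sequence")
    stop("the sequence-ordered strategy requires the many-chains scheme")
  structure(list(maxIterations = as.integer(maxIterations),
                 axisTolerance = axisTolerance,
                 csmTolerance = csmTolerance,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 strategy = strategy, manyChains = manyChains),
            class = "csmConfig")
}

#' Initial axis guess by centroid regression
#'
#' Computes the centroid of every equivalence class and returns the
#' direction of the best-fit line through them (orthogonal-distance fit:
#' principal eigenvector of the centroid scatter). For a perfectly
#' symmetric structure the class centroids lie exactly on the symmetry
#' axis, so the fit recovers it.
#'
#' For improper groups the class centroids lie in the mirror plane
#' rather than on the axis, so the guess is the normal of the best-fit
#' plane (smallest principal direction) instead: set `mode = "plane"`.
#'
#' @param structure a prepared [ProteinStructure-class].
#' @param partition its [EquivalencePartition-class].
#' @param mode "line" (proper rotations; principal direction of the
#'   class centroids) or "plane" (improper; normal of their best-fit
#'   plane).
#' @return unit 3-vector with attribute `degenerate` (TRUE when the
#'   centroids coincide and the z axis is returned as fallback).
#' @export
initialAxis <- function(structure, partition, mode = c("line", "plane")) {
  mode <- match.arg(mode)
  if (nClasses(partition) < 2L)
    stop("need at least two equivalence classes for the axis regression")
  Q <- coords(structure)
  ctrs <- t(vapply(partition@classes, function(cls)
    colMeans(Q[cls, , drop = FALSE]), numeric(3)))
  ctrs <- sweep(ctrs, 2, colMeans(ctrs))
  sc <- crossprod(ctrs) / nrow(ctrs)
  tot <- sum(diag(sc))
  if (tot < 1e-18) {
    v <- c(0, 0, 1)
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  e <- eigen(sc, symmetric = TRUE)
  v <- canonicalAxis(unitVector(e$vectors[, if (mode == "line") 1 else 3]))
  attr(v, "degenerate") <- FALSE
  v
}

# restart directions: the regression guess, cones of increasing opening
# around it, and fully random unit vectors; deterministic under seed
restartDirections <- function(v0, restarts, seed) {
  if (restarts == 1L) return(list(v0))
  withSeed(seed, {
    out <- vector("list", restarts)
    out[[1]] <- v0
    F <- orthonormalFrame(v0)
    nCone <- min(restarts - 1L, ceiling((restarts - 1L) / 2))
    angles <- seq(15, 75, length.out = max(nCone, 1)) * pi / 180
    k <- 1L
    for (i in seq_len(nCone)) {
      phi <- stats::runif(1, 0, 2 * pi)
      a <- angles[i]
      d <- sin(a) * (cos(phi) * F[, 1] + sin(phi) * F[, 2]) + cos(a) * v0
      k <- k + 1L
      out[[k]] <- unitVector(d)
    }
    while (k < restarts) {
      d <- stats::rnorm(3)
      k <- k + 1L
      out[[k]] <- unitVector(d)
    }
    out
  })
}

computeAssignment <- function(structure, partition, op, config) {
  if (config$manyChains) {
    if (config$strategy == "sequence") {
      # peptide level still optimised: costs from ordinal maps
      tl <- manyChainsAssignSequence(structure, partition, op)
    } else {
      tl <- manyChainsAssign(structure, partition, op, config$strategy)
    }
  } else {
    tl <- flatClassAssign(structure, partition, op, config$strategy)
  }
  tl
}

# sequence-ordered atom maps with Hungarian-optimised peptide level
manyChainsAssignSequence <- function(structure, partition, op) {
  peps <- peptideIndices(structure)
  ell <- length(peps)
  Q <- coords(structure)
  TQ <- applyOperation(op, Q, 1L)
  B <- matrix(0, ell, ell)
  for (i in seq_len(ell))
    for (j in seq_len(ell))
      B[i, j] <- sum((TQ[peps[[i]], , drop = FALSE] -
                      Q[peps[[j]], , drop = FALSE])^2)
  pperm <- as.integer(hungarianAssign(B))
  tl <- sequenceOrderedAssign(structure, partition, pperm)
  tl@pairCosts <- B
  tl
}

solveOneStart <- function(structure, partition, group, v0, config, origin) {
  v <- unitVector(v0)
  best <- NULL
  sPrev <- Inf
  iterations <- 0L
  converged <- FALSE
  degenerate <- FALSE
  for (it in seq_len(config$maxIterations)) {
    iterations <- it
    op <- symmetryOperation(group, v, origin)
    tl <- computeAssignment(structure, partition, op, config)
    axOp <- optimalAxis(structure, group, tl@global, init = v)
    degenerate <- degenerate || isTRUE(attr(axOp, "degenerate"))
    res <- evaluateCSM(structure, axOp, tl@global, strategy = config$strategy)
    res@peptidePerm <- tl@peptidePerm
    if (is.null(best) || res@sValue < best@sValue) best <- res
    dAxis <- axisAngle(axOp@axis, v)
    dS <- abs(sPrev - res@sValue)
    if (res@sValue > sPrev + 1e-12) {        # oscillation guard
      converged <- FALSE
      break
    }
    if (dAxis < config$axisTolerance || dS < config$csmTolerance) {
      converged <- TRUE
      break
    }
    v <- axOp@axis
    sPrev <- res@sValue
  }
  best@iterations <- iterations
  best@converged <- converged
  best@degenerate <- degenerate
  best
}

#' Solve for the CSM of a prepared homomer
#'
#' Runs the alternating permutation/axis optimisation from the
#' centroid-regression initial axis plus seeded restarts and returns the
#' minimum-S result: S(G), the optimal operation (axis), the global atom
#' permutation, the peptide permutation and the nearest G-symmetric
#' structure.
#'
#' @param structure a prepared [ProteinStructure-class] with >= 2
#'   peptides (see [prepareStructure()]).
#' @param group a [PointGroup-class] or label ("c4", "s2", ...).
#' @param config a [csmConfig()] list.
#' @param partition optional precomputed [EquivalencePartition-class].
#' @return a [CSMResult-class].
#' @examples
#' gen <- syntheticHomomer(groupOrder = 3, residuesPerChain = 4,
#'                         noiseSigma = 0, seed = 7)
#' res <- solveCSM(gen$structure, "c3")
#' csmValue(res)   # ~ 0 for an exact C3 orbit
#' @export
solveCSM <- function(structure, group, config = csmConfig(),
                     partition = NULL) {
  if (is.character(group)) group <- parseGroup(group)
  assertPrepared(structure)
  if (nPeptides(structure) < 2L)
    stop("single-peptide structures (internal symmetry) are out of scope")
  if (is.null(partition)) partition <- buildPartition(structure)
  origin <- centroid(structure)
  v0 <- initialAxis(structure, partition,
                    mode = if (group@kind == "S") "plane" else "line")
  starts <- restartDirections(unitVector(as.numeric(v0)), config$restarts,
                              config$seed)
  best <- NULL
  for (s in starts) {
    res <- solveOneStart(structure, partition, group, s, config, origin)
    if (is.null(best) || res@sValue < best@sValue) best <- res
  }
  canonicalizeResult(structure, group, config, best, origin)
}

# Report the axis with canonical sign. v and -v describe the same group
# (T(-v) = T(v)^{-1}), so flipping the axis while inverting the
# permutation leaves every orbit term, hence S, unchanged.
canonicalizeResult <- function(structure, group, config, best, origin) {
  vC <- canonicalAxis(best@operation@axis)
  if (all(vC == best@operation@axis)) return(best)
  inv <- integer(length(best@permutation))
  inv[best@permutation] <- seq_along(best@permutation)
  resC <- evaluateCSM(structure, symmetryOperation(group, vC, origin), inv,
                      strategy = config$strategy)
  if (resC@sValue > best@sValue + 1e-12 * (1 + best@sValue)) return(best)
  if (length(best@peptidePerm)) {
    pinv <- integer(length(best@peptidePerm))
    pinv[best@peptidePerm] <- seq_along(best@peptidePerm)
    resC@peptidePerm <- pinv
  }
  resC@iterations <- best@iterations
  resC@converged <- best@converged
  resC@degenerate <- best@degenerate
  resC
}

#' Continuous Chirality Measure
#'
#' Runs [solveCSM()] for the two improper chirality targets, the mirror
#' group S1 and the inversion group S2, and returns the minimum-S
#' result. A value of zero means the structure is achiral.
#'
#' @inheritParams solveCSM
#' @return a [CSMResult-class] (the smaller of the S1 and S2 results).
#' @export
solveChirality <- function(structure, config = csmConfig(),
                           partition = NULL) {
  if (is.null(partition)) partition <- buildPartition(structure)
  r1 <- solveCSM(structure, pointGroup("S", 1), config, partition)
  r2 <- solveCSM(structure, pointGroup("S", 2), config, partition)
  if (r1@sValue <= r2@sValue) r1 else r2
}

#' @describeIn solveCSM the S(G) value of a result.
#' @param x a [CSMResult-class].
#' @export
setMethod("csmValue", "CSMResult", function(x) x@sValue)

#' @describeIn solveCSM the optimal unit axis.
#' @export
setMethod("symmetryAxis", "CSMResult", function(x) x@operation@axis)

#' @describeIn solveCSM the global atom permutation pi.
#' @export
setMethod("atomPermutation", "CSMResult", function(x) x@permutation)

#' @describeIn solveCSM the peptide-level permutation (may be empty).
#' @export
setMethod("peptidePermutation", "CSMResult", function(x) x@peptidePerm)

#' @describeIn solveCSM the nearest-symmetric coordinates (N x 3).
#' @export
setMethod("nearestCoords", "CSMResult", function(x) x@nearest)

setMethod("show", "CSMResult", function(object) {
  g <- object@operation@group
  cat(sprintf("CSMResult  S(%s%d) = %.4f\n", g@kind, g@n, object@sValue))
  cat(sprintf("  M(G) = %.6g A^2   N(G) = %.6g A^2\n",
              object@mValue, object@normValue))
  cat("  axis:", sprintf("%.6f", object@operation@axis), "\n")
  if (length(object@peptidePerm))
    cat("  peptide permutation:", cycleNotation(object@peptidePerm), "\n")
  cat("  iterations:", object@iterations,
      " converged:", object@converged,
      if (object@degenerate) " (degenerate axis)" else "", "\n")
})

#' Serialise a CSM result to JSON
#'
#' @param result a [CSMResult-class].
#' @param structure optional structure for chain-labelled cycle
#'   notation.
#' @param path optional output path.
#' @return JSON string.
#' @export
csmResultJSON <- function(result, structure = NULL, path = NULL) {
  g <- result@operation@group
  obj <- list(s_value = result@sValue,
              m_value = result@mValue,
              norm_value = result@normValue,
              group = paste0(g@kind, g@n),
              axis = result@operation@axis,
              origin = result@operation@origin,
              peptide_permutation = if (length(result@peptidePerm)) {
                if (!is.null(structure))
                  peptideCycleNotation(structure, result@peptidePerm)
                else cycleNotation(result@peptidePerm)
              } else NULL,
              iterations = result@iterations,
              converged = result@converged,
              degenerate = result@degenerate,
              strategy = result@strategy)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
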