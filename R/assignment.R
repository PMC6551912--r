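# Class-preserving atom permutations for a fixed symmetry operation.
#
# Strategies for the atom level:
#   hungarian - exact assignment per equivalence class (optimal),
#   greedy    - smallest-remaining-entry heuristic,
#   sequence  - atoms interchanged by their within-chain serial order.
# The two-level "many chains" scheme computes, for every ordered peptide
# pair (i, j), the best class-preserving atom map and its cost B[i, j]
# (lower level), then solves the assignment problem on B for the peptide
# permutation (higher level) and composes the stored pair maps into the
# global atom permutation, which therefore never mixes peptides.

ASSIGN_STRATEGIES <- c("hungarian", "greedy", "sequence")

# Within-peptide ordinals of the class members. For a prepared structure
# every class occupies the same ordinals in every peptide.
classOrdinals <- function(structure, partition) {
  peps <- peptideIndices(structure)
  M <- length(peps[[1]])
  ell <- length(peps)
  pepOf <- integer(nAtoms(structure))
  ordOf <- integer(nAtoms(structure))
  for (p in seq_along(peps)) {
    pepOf[peps[[p]]] <- p
    ordOf[peps[[p]]] <- seq_len(M)
  }
  ords <- lapply(partition@classes, function(cls) {
    o <- sort(unique(ordOf[cls]))
    if (length(o) * ell != length(cls))
      stop("class does not occupy identical ordinals in every peptide")
    o
  })
  list(ordinals = ords, pepOf = pepOf, ordOf = ordOf,
       pepIdx = peps, M = M, ell = ell)
}

# atom map within one class restricted to a peptide pair, by strategy;
# cost matrix rows = source atoms (peptide i), cols = target (peptide j)
pairClassMap <- function(costMat, strategy) {
  s <- nrow(costMat)
  if (s == 1L) return(list(map = 1L, cost = costMat[1, 1]))
  mu <- switch(strategy,
               hungarian = hungarianAssign(costMat),
               greedy = greedyAssign(costMat),
               sequence = {
                 m <- seq_len(s)
                 attr(m, "cost") <- sum(diag(costMat))
                 m
               })
  list(map = as.integer(mu), cost = attr(mu, "cost"))
}

#' Two-level ("many chains") assignment
#'
#' Computes the class-preserving atom permutation for a fixed symmetry
#' operation while guaranteeing that each peptide is carried in its
#' entirety onto another peptide. The lower level finds, for every
#' ordered peptide pair, the best atom map restricted to the equivalence
#' classes (by the chosen strategy; "hungarian" is exact, and since the
#' class-preserving minimum factorises over classes the per-pair map is
#' optimal). The higher level runs the Hungarian algorithm on the pair
#' cost matrix B to pick the peptide permutation, and the two are
#' composed into the global atom permutation.
#'
#' Costs use only the first power of the operation (the i = 1 term of
#' the orbit objective); the full orbit sum is used for final scoring by
#' [evaluateCSM()].
#'
#' @param structure a prepared [ProteinStructure-class].
#' @param partition the [EquivalencePartition-class] of `structure`.
#' @param op a [SymmetryOperation-class].
#' @param strategy one of "hungarian", "greedy", "sequence".
#' @return a [TwoLevelPermutation-class].
#' @export
manyChainsAssign <- function(structure, partition, op,
                             strategy = c("hungarian", "greedy", "sequence")) {
  strategy <- match.arg(strategy)
  assertPrepared(structure)
  info <- classOrdinals(structure, partition)
  ell <- info$ell
  M <- info$M
  peps <- info$pepIdx
  if (ell == 1L) {
    warning("single peptide: identity peptide permutation (internal symmetry is out of scope)")
    return(new("TwoLevelPermutation", peptidePerm = 1L,
               global = seq_len(nAtoms(structure)),
               pairCosts = matrix(0, 1, 1)))
  }
  Q <- coords(structure)
  TQ <- applyOperation(op, Q, 1L)
  sizes <- lengths(info$ordinals)
  ord1 <- unlist(info$ordinals[sizes == 1L], use.names = FALSE)
  multi <- which(sizes > 1L)

  B <- matrix(0, ell, ell)
  # pairMaps[[i]][[j]] = ordinal map nu: source ordinal o (peptide i) ->
  # target ordinal nu[o] (peptide j)
  pairMaps <- vector("list", ell)
  for (i in seq_len(ell)) {
    pairMaps[[i]] <- vector("list", ell)
    srcIdx <- peps[[i]]
    for (j in seq_len(ell)) {
      tgtIdx <- peps[[j]]
      nu <- seq_len(M)
      cost <- if (length(ord1))
        sum((TQ[srcIdx[ord1], , drop = FALSE] -
             Q[tgtIdx[ord1], , drop = FALSE])^2) else 0
      for (ci in multi) {
        o <- info$ordinals[[ci]]
        cm <- matrix(0, length(o), length(o))
        for (a in seq_along(o)) {
          diffs <- sweep(Q[tgtIdx[o], , drop = FALSE], 2, TQ[srcIdx[o[a]], ])
          cm[a, ] <- rowSums(diffs^2)
        }
        res <- pairClassMap(cm, strategy)
        nu[o] <- o[res$map]
        cost <- cost + res$cost
      }
      B[i, j] <- cost
      pairMaps[[i]][[j]] <- nu
    }
  }
  pperm <- as.integer(hungarianAssign(B))
  global <- integer(nAtoms(structure))
  for (i in seq_len(ell)) {
    j <- pperm[i]
    nu <- pairMaps[[i]][[j]]
    global[peps[[i]]] <- peps[[j]][nu]
  }
  new("TwoLevelPermutation", peptidePerm = pperm, global = global,
      pairCosts = B)
}

#' Sequence-ordered atom permutation
#'
#' Baseline mapping: within each peptide pair dictated by
#' `peptidePerm`, the atom at within-chain ordinal o of peptide i maps
#' to the atom at the same ordinal of the target peptide; no geometric
#' cost minimisation at the atom level.
#'
#' @param structure a prepared [ProteinStructure-class].
#' @param partition the structure's partition (validated only).
#' @param peptidePerm integer permutation of the peptides.
#' @return a [TwoLevelPermutation-class].
#' @export
sequenceOrderedAssign <- function(structure, partition, peptidePerm) {
  assertPrepared(structure)
  peps <- peptideIndices(structure)
  ell <- length(peps)
  stopifnot(length(peptidePerm) == ell, setequal(peptidePerm, seq_len(ell)))
  if (length(unique(lengths(peps))) != 1L)
    stop("peptides have different lengths; run prepareStructure() first")
  global <- integer(nAtoms(structure))
  for (i in seq_len(ell)) global[peps[[i]]] <- peps[[peptidePerm[i]]]
  new("TwoLevelPermutation", peptidePerm = as.integer(peptidePerm),
      global = global, pairCosts = matrix(numeric(0), 0, 0))
}

#' Flat per-class assignment (no peptide level)
#'
#' Computes the permutation independently within every full equivalence
#' class (size l or 2l), with no guarantee that peptides map onto whole
#' peptides. This is the single-level scheme the two-level algorithm
#' improves on; it is kept for comparison.
#'
#' @inheritParams manyChainsAssign
#' @param strategy "hungarian" or "greedy".
#' @return a [TwoLevelPermutation-class] with empty `peptidePerm`.
#' @export
flatClassAssign <- function(structure, partition, op,
                            strategy = c("hungarian", "greedy")) {
  strategy <- match.arg(strategy)
  Q <- coords(structure)
  TQ <- applyOperation(op, Q, 1L)
  global <- integer(nAtoms(structure))
  for (cls in partition@classes) {
    k <- length(cls)
    cm <- matrix(0, k, k)
    for (a in seq_len(k)) {
      diffs <- sweep(Q[cls, , drop = FALSE], 2, TQ[cls[a], ])
      cm[a, ] <- rowSums(diffs^2)
    }
    mu <- if (strategy == "hungarian") hungarianAssign(cm) else greedyAssign(cm)
    global[cls] <- cls[mu]
  }
  new("TwoLevelPermutation", peptidePerm = integer(0), global = global,
      pairCosts = matrix(numeric(0), 0, 0))
}

setMethod("show", "TwoLevelPermutation", function(object) {
  cat("TwoLevelPermutation\n  atoms:", length(object@global), "\n")
  if (length(object@peptidePerm))
    cat("  peptide permutation:", cycleNotation(object@peptidePerm), "\n")
})

#' Report a permutation in peptide cycle notation
#'
#' @param structure the structure the permutation belongs to.
#' @param twoLevel a [TwoLevelPermutation-class] (or integer peptide
#'   permutation).
#' @return character like "A -> C -> D -> B -> E".
#' @export
peptideCycleNotation <- function(structure, twoLevel) {
  p <- if (is(twoLevel, "TwoLevelPermutation")) twoLevel@peptidePerm
       else as.integer(twoLevel)
  if (!length(p)) return("")
  cycleNotation(p, labels = chainIds(structure))
}
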