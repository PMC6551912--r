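# small internal helpers

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vecNorm <- function(v) sqrt(sum(v^2))

unitVector <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-300) stop("cannot normalise a zero vector")
  v / n
}

# Canonical sign: first component larger than `tol` in absolute value is
# made positive, so v and -v (the same axis line) print identically.
canonicalAxis <- function(v, tol = 1e-9) {
  for (i in 1:3) {
    if (abs(v[i]) > tol) {
      if (v[i] < 0) v <- -v
      break
    }
  }
  v
}

# Angle in radians between two axis *lines* (sign-insensitive).
axisAngle <- function(a, b) {
  d <- abs(sum(unitVector(a) * unitVector(b)))
  acos(min(1, d))
}

# Any orthonormal completion of a unit vector.
orthonormalFrame <- function(v) {
  v <- unitVector(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitVector(ref - sum(ref * v) * v)
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  cbind(e1, e2, v)
}

# Apply an integer permutation i times (pi^i).
permPower <- function(p, i) {
  out <- seq_along(p)
  while (i > 0) {
    out <- p[out]
    i <- i - 1
  }
  out
}

# Cycle decomposition of an integer permutation, as a list of vectors.
permCycles <- function(p) {
  n <- length(p)
  seen <- logical(n)
  cycles <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    cyc <- s
    seen[s] <- TRUE
    k <- p[s]
    while (k != s) {
      cyc <- c(cyc, k)
      seen[k] <- TRUE
      k <- p[k]
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

# "A -> C -> D -> B -> E" style cycle notation over labels.
cycleNotation <- function(p, labels = as.character(seq_along(p))) {
  cycles <- permCycles(p)
  txt <- vapply(cycles, function(cyc) {
    if (length(cyc) == 1L) labels[cyc]
    else paste(labels[cyc], collapse = " -> ")
  }, character(1))
  paste(txt, collapse = "; ")
}
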