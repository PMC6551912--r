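# Accessors, show methods and basic geometry for ProteinStructure.

#' @describeIn ProteinStructure the atom table (one row per atom).
#' @param x,object a \code{ProteinStructure}.
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' @describeIn ProteinStructure total atom count N.
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' @describeIn ProteinStructure N x 3 coordinate matrix (Angstrom).
#' @export
setMethod("coords", "ProteinStructure", function(x) {
  cbind(x = x@atoms$x, y = x@atoms$y, z = x@atoms$z)
})

#' @describeIn ProteinStructure chain identifiers in order of first
#'   appearance in the file.
#' @export
setMethod("chainIds", "ProteinStructure", function(x) {
  unique(x@atoms$chainId)
})

#' @describeIn ProteinStructure number of peptides (chains).
#' @export
setMethod("nPeptides", "ProteinStructure", function(x) {
  length(unique(x@atoms$chainId))
})

#' @describeIn ProteinStructure list of per-peptide atom index vectors,
#'   in chain order of first appearance.
#' @export
setMethod("peptideIndices", "ProteinStructure", function(x) {
  ids <- chainIds(x)
  out <- lapply(ids, function(ch) which(x@atoms$chainId == ch))
  names(out) <- ids
  out
})

#' @describeIn ProteinStructure unweighted geometric centroid of all
#'   atoms (3-vector, Angstrom).
#' @export
setMethod("centroid", "ProteinStructure", function(x) {
  if (!nAtoms(x)) stop("empty structure has no centroid")
  colMeans(coords(x))
})

setMethod("show", "ProteinStructure", function(object) {
  peps <- peptideIndices(object)
  lens <- lengths(peps)
  cat("ProteinStructure", if (!is.na(object@sourceId)) object@sourceId else "",
      "\n  atoms:", nAtoms(object),
      " peptides:", length(peps),
      if (length(lens) && length(unique(lens)) == 1L)
        paste0(" (", lens[1], " atoms each)") else
        paste0(" (lengths ", paste(lens, collapse = "/"), ")"),
      "\n  chains:", paste(names(peps), collapse = " "), "\n")
})

# Replace the coordinates of a structure (same atom order).
setCoords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nAtoms(structure))
  structure@atoms$x <- xyz[, 1]
  structure@atoms$y <- xyz[, 2]
  structure@atoms$z <- xyz[, 3]
  structure
}

#' Rigidly transform a structure
#'
#' Applies \code{x -> R x + t} to every atom. Used for invariance checks
#' and fixture construction.
#'
#' @param structure a [ProteinStructure-class].
#' @param rotation 3 x 3 orthogonal matrix (default identity).
#' @param translation 3-vector (default zero).
#' @param scale positive scalar applied before the rotation.
#' @return the transformed structure.
#' @export
transformStructure <- function(structure, rotation = diag(3),
                               translation = c(0, 0, 0), scale = 1) {
  xyz <- coords(structure) * scale
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  setCoords(structure, xyz)
}

#' Reflect a structure through a plane
#'
#' Mirrors every atom through the plane with the given unit normal
#' passing through `point`. Used to test parity invariance of the
#' chirality measure.
#'
#' @param structure a [ProteinStructure-class].
#' @param normal plane normal (default x).
#' @param point a point on the plane (default the structure centroid).
#' @return the reflected structure.
#' @export
reflectStructure <- function(structure, normal = c(1, 0, 0), point = NULL) {
  if (is.null(point)) point <- centroid(structure)
  nrm <- unitVector(normal)
  xyz <- sweep(coords(structure), 2, point)
  xyz <- xyz - 2 * (xyz %*% nrm) %*% t(nrm)
  setCoords(structure, sweep(xyz, 2, point, "+"))
}

# Identity key of each atom used by prep and equivalence:
# (resSeq, iCode, resName, name).
atomIdentity <- function(at) {
  paste(at$resSeq, at$iCode, at$resName, at$name, sep = "|")
}

#' Is a structure prepared for CSM analysis?
#'
#' A prepared structure has peptides of identical length with identical
#' (residue name, residue number, atom name) sequences, so that atoms
#' correspond across chains position by position. A single-chain
#' structure satisfies this vacuously (but is rejected by the solver,
#' which needs at least two peptides).
#'
#' @param structure a [ProteinStructure-class].
#' @return logical scalar.
#' @export
isPrepared <- function(structure) {
  peps <- peptideIndices(structure)
  if (length(peps) < 1L) return(FALSE)
  if (length(peps) == 1L) return(TRUE)
  at <- structure@atoms
  ids <- lapply(peps, function(ix) atomIdentity(at[ix, ]))
  if (length(unique(lengths(ids))) != 1L) return(FALSE)
  all(vapply(ids[-1], identical, logical(1), ids[[1]]))
}

assertPrepared <- function(structure) {
  if (!isPrepared(structure))
    stop("structure is not prepared (run prepareStructure(): chains must ",
         "have identical residue/atom sequences)")
  invisible(structure)
}
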