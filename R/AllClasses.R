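#' @import methods
NULL

ATOM_COLUMNS <- c("record", "serial", "name", "altLoc", "resName", "chainId",
                  "resSeq", "iCode", "x", "y", "z", "occupancy", "tempFactor",
                  "element")

emptyAtomTable <- function() {
  data.frame(record = character(), serial = integer(), name = character(),
             altLoc = character(), resName = character(), chainId = character(),
             resSeq = integer(), iCode = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), tempFactor = numeric(),
             element = character(), stringsAsFactors = FALSE)
}

#' ProteinStructure: an ordered multi-chain atom set
#'
#' Holds the atoms of a (possibly multi-chain) protein structure in file
#' order, one row per atom, together with the identifiers needed for
#' symmetry analysis. Peptides are the maximal runs of atoms sharing a
#' chain identifier, ordered by first appearance in the file.
#'
#' @slot atoms data.frame with one row per atom and columns
#'   \code{record, serial, name, altLoc, resName, chainId, resSeq, iCode,
#'   x, y, z, occupancy, tempFactor, element}.
#' @slot sourceId character scalar, PDB ID or file name.
#' @slot remarks list with optional elements \code{missingResidues} and
#'   \code{missingAtoms} parsed from REMARK 465/470 records.
#'
#' @seealso [readPDB()], [prepareStructure()], [solveCSM()]
#' @export
setClass("ProteinStructure",
         representation(atoms = "data.frame", sourceId = "character",
                        remarks = "list"),
         prototype(atoms = emptyAtomTable(), sourceId = NA_character_,
                   remarks = list()))

setValidity("ProteinStructure", function(object) {
  at <- object@atoms
  msg <- character()
  miss <- setdiff(ATOM_COLUMNS, names(at))
  if (length(miss))
    msg <- c(msg, paste("atom table lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(at)) {
    if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
      msg <- c(msg, "non-finite coordinates")
    if (any(!nzchar(at$element)))
      msg <- c(msg, "empty element symbols")
  }
  if (length(msg)) msg else TRUE
})

#' PointGroup: a cyclic point group Cn or Sn
#'
#' The cyclic symmetry groups handled by the package: proper rotations
#' Cn (rotation by 360/n degrees) and improper rotations Sn (rotation
#' composed with reflection through the plane perpendicular to the
#' axis). S1 is the mirror group and S2 the inversion group, the two
#' chirality targets; genuine Sn requires even n.
#'
#' @slot kind "C" (proper) or "S" (improper).
#' @slot n integer group index (rotation angle is 360/n degrees).
#' @export
setClass("PointGroup", representation(kind = "character", n = "integer"))

setValidity("PointGroup", function(object) {
  if (!object@kind %in% c("C", "S")) return("kind must be 'C' or 'S'")
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 1L) return("n must be a positive integer")
  if (object@kind == "C" && n < 2L) return("Cn requires n >= 2")
  if (object@kind == "S" && n > 2L && n %% 2L == 1L)
    return("Sn with odd n > 2 does not generate a finite improper cyclic group here; use S1 (mirror) or S2 (inversion)")
  TRUE
})

#' SymmetryOperation: a concrete generator T of a cyclic group
#'
#' A rotation (proper or improper) by 360/n degrees about a unit axis
#' through a fixed origin (the structure centroid in all package code
#' paths).
#'
#' @slot group a [PointGroup-class].
#' @slot axis unit 3-vector, the direction of the symmetry axis.
#' @slot origin 3-vector, the point the axis passes through.
#' @export
setClass("SymmetryOperation",
         representation(group = "PointGroup", axis = "numeric",
                        origin = "numeric"))

setValidity("SymmetryOperation", function(object) {
  if (length(object@axis) != 3L || !all(is.finite(object@axis)))
    return("axis must be a finite 3-vector")
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
    return("axis must have unit length")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be a finite 3-vector")
  TRUE
})

#' EquivalencePartition: sequence-aware atom equivalence classes
#'
#' A partition of the atom indices of a prepared structure into the
#' classes a symmetry permutation may act within: atoms share a class
#' iff they agree on element, residue name, residue sequence number
#' (with insertion code) and canonical atom label, where chemically
#' interchangeable branch atoms (e.g. the two Val C-gamma) share one
#' canonical label.
#'
#' @slot classes list of integer vectors of atom indices (disjoint cover).
#' @slot keys data.frame, one row per class: \code{element, resName,
#'   resSeq, iCode, label}.
#' @export
setClass("EquivalencePartition",
         representation(classes = "list", keys = "data.frame",
                        nAtoms = "integer"))

setValidity("EquivalencePartition", function(object) {
  idx <- unlist(object@classes, use.names = FALSE)
  if (length(idx) != object@nAtoms || anyDuplicated(idx) ||
      !setequal(idx, seq_len(object@nAtoms)))
    return("classes must form a disjoint cover of the atom indices")
  if (nrow(object@keys) != length(object@classes))
    return("one key row per class required")
  TRUE
})

#' TwoLevelPermutation: peptide permutation plus per-pair atom maps
#'
#' The result of the two-level ("many chains") assignment: a permutation
#' of the peptides, for each peptide pair (i, peptidePerm[i]) a
#' class-preserving atom map, and the composed global atom permutation.
#'
#' @slot peptidePerm integer permutation of the peptide indices.
#' @slot global integer permutation of all atom indices; entry k is
#'   pi(k), the atom whose ideal position is T applied to atom k.
#' @slot pairCosts numeric matrix B of per-pair assignment costs
#'   (Angstrom^2), or a 0x0 matrix when not applicable.
#' @export
setClass("TwoLevelPermutation",
         representation(peptidePerm = "integer", global = "integer",
                        pairCosts = "matrix"))

setValidity("TwoLevelPermutation", function(object) {
  g <- object@global
  if (length(g) && (anyDuplicated(g) || !setequal(g, seq_along(g))))
    return("global must be a permutation of 1..N")
  p <- object@peptidePerm
  if (length(p) && (anyDuplicated(p) || !setequal(p, seq_along(p))))
    return("peptidePerm must be a permutation of 1..l")
  TRUE
})

#' CSMResult: a Continuous Symmetry Measure evaluation
#'
#' The outcome of evaluating (or optimising) the CSM of a structure for
#' a cyclic point group: S(G) = 100 * M(G) / N(G), on the 0--100 scale,
#' with the operation, the atom permutation and the nearest G-symmetric
#' coordinate set.
#'
#' @slot sValue the CSM S(G), dimensionless in [0, 100].
#' @slot mValue numerator M(G), Angstrom^2.
#' @slot normValue denominator N(G), Angstrom^2 (spread about centroid).
#' @slot operation the [SymmetryOperation-class] used.
#' @slot permutation integer global atom permutation pi.
#' @slot peptidePerm integer peptide-level permutation (length 0 when
#'   the permutation was not built per peptide).
#' @slot nearest numeric N x 3 matrix of nearest-symmetric coordinates.
#' @slot iterations integer, solver iterations (0 for plain evaluation).
#' @slot converged logical.
#' @slot degenerate logical, TRUE when the axis is not determined by the
#'   objective (e.g. inversion).
#' @slot strategy character, atom assignment strategy used.
#' @export
setClass("CSMResult",
         representation(sValue = "numeric", mValue = "numeric",
                        normValue = "numeric", operation = "SymmetryOperation",
                        permutation = "integer", peptidePerm = "integer",
                        nearest = "matrix", iterations = "integer",
                        converged = "logical", degenerate = "logical",
                        strategy = "character"))

setValidity("CSMResult", function(object) {
  if (object@normValue <= 0) return("normValue must be positive")
  s <- object@sValue
  if (abs(s - 100 * object@mValue / object@normValue) > 1e-6 * (1 + s))
    return("sValue must equal 100 * mValue / normValue")
  if (s < -1e-9 || s > 100 + 1e-6) return("sValue must lie in [0, 100]")
  TRUE
})

#' PrepReport: record of the structure preparation pipeline
#'
#' Counts and listings of everything removed while making a raw PDB
#' structure ready for CSM analysis.
#'
#' @slot removedHetatm integer count of HETATM/solvent records removed.
#' @slot removedHydrogens integer count of hydrogens removed.
#' @slot removedAltloc integer count of alternate-location atoms dropped.
#' @slot prunedResidues data.frame (\code{resName, resSeq, iCode, reason}).
#' @slot prunedAtoms data.frame (\code{chainId, resSeq, iCode, name}).
#' @slot finalPeptideLength integer common per-chain atom count.
#' @slot chainsKept character vector of chain identifiers.
#' @export
setClass("PrepReport",
         representation(removedHetatm = "integer", removedHydrogens = "integer",
                        removedAltloc = "integer", prunedResidues = "data.frame",
                        prunedAtoms = "data.frame",
                        finalPeptideLength = "integer", chainsKept = "character"),
         prototype(removedHetatm = 0L, removedHydrogens = 0L,
                   removedAltloc = 0L,
                   prunedResidues = data.frame(resName = character(),
                                               resSeq = integer(),
                                               iCode = character(),
                                               reason = character()),
                   prunedAtoms = data.frame(chainId = character(),
                                            resSeq = integer(),
                                            iCode = character(),
                                            name = character()),
                   finalPeptideLength = NA_integer_,
                   chainsKept = character()))
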