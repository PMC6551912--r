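# Sequence-aware equivalence classes. Atoms may only be permuted within
# a class, and classes are keyed by (element, residue name, residue
# number + insertion code, canonical atom label). Chemically
# interchangeable branch atoms of symmetric side chains share one
# canonical label, so a class holds l atoms (one per peptide) or 2l
# atoms (an interchangeable pair per peptide).

# Interchangeable atom-name groups per residue type. This is an explicit
# chemical table, not digit stripping: Ile CG1/CG2 are topologically
# different branches and must NOT be merged, while these pairs sit on
# locally symmetric side chains. Asn OD1/ND2 and Gln OE1/NE2 differ in
# element; His ring atoms are chemically distinct: none are merged.
INTERCHANGEABLE_TABLE <- list(
  VAL = list(c("CG1", "CG2")),
  LEU = list(c("CD1", "CD2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ARG = list(c("NH1", "NH2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2"))
)

#' Interchangeable atom-name groups of a residue type
#'
#' Returns the groups of atom names within the residue's side chain
#' whose labels are chemically interchangeable by local symmetry (free
#' rotation or ring flip): Val CG1/CG2, Leu CD1/CD2, Phe/Tyr CD1/CD2 and
#' CE1/CE2, Arg NH1/NH2, Asp OD1/OD2, Glu OE1/OE2. All other residues
#' (including Ile, whose two C-gamma branches are topologically
#' distinct) have none.
#'
#' @param resName 3-letter residue code.
#' @return list of character vectors (possibly empty).
#' @examples
#' interchangeableAtoms("VAL")
#' interchangeableAtoms("ILE")
#' @export
interchangeableAtoms <- function(resName) {
  grp <- INTERCHANGEABLE_TABLE[[toupper(resName)]]
  if (is.null(grp)) list() else grp
}

# Canonical label of one atom: its name unless it belongs to an
# interchangeable group of its residue type, in which case the group's
# joined name ("CG1|CG2").
canonicalLabel <- function(name, resName) {
  for (grp in interchangeableAtoms(resName))
    if (name %in% grp) return(paste(grp, collapse = "|"))
  name
}

#' Build the equivalence partition of a prepared structure
#'
#' Assigns every atom to exactly one class keyed by (element, residue
#' name, residue number + insertion code, canonical atom label). Classes
#' are listed deterministically by residue number, insertion code, then
#' label. For hydrogen-free prepared homomers every class holds exactly
#' one atom per peptide, or two for interchangeable branch pairs.
#'
#' @param structure a prepared [ProteinStructure-class].
#' @return an [EquivalencePartition-class].
#' @export
buildPartition <- function(structure) {
  assertPrepared(structure)
  at <- structure@atoms
  unknown <- unique(at$resName[!(at$resName %in% STANDARD_AA)])
  if (length(unknown)) {
    digitNamed <- unknown[vapply(unknown, function(rn)
      any(grepl("[0-9]$", at$name[at$resName == rn])), logical(1))]
    if (length(digitNamed))
      warning("unknown residue type(s) with digit-suffixed atom names (",
              paste(digitNamed, collapse = ", "),
              "): branch atoms kept in distinct classes")
  }
  labels <- mapply(canonicalLabel, at$name, at$resName, USE.NAMES = FALSE)
  key <- paste(at$element, at$resName, at$resSeq, at$iCode, labels, sep = "\r")
  ord <- order(at$resSeq, at$iCode, labels, at$element, method = "radix")
  classKeys <- key[ord][!duplicated(key[ord])]
  classes <- split(seq_len(nrow(at)), factor(key, levels = classKeys))
  names(classes) <- NULL
  parts <- do.call(rbind, strsplit(classKeys, "\r", fixed = TRUE))
  keys <- data.frame(element = parts[, 1], resName = parts[, 2],
                     resSeq = as.integer(parts[, 3]), iCode = parts[, 4],
                     label = parts[, 5], stringsAsFactors = FALSE)
  part <- new("EquivalencePartition", classes = classes, keys = keys,
              nAtoms = nrow(at))
  validatePartitionBalance(part, structure)
  part
}

# Every class must contain the same number of atoms from each peptide.
validatePartitionBalance <- function(partition, structure) {
  chain <- structure@atoms$chainId
  ids <- chainIds(structure)
  for (ci in seq_along(partition@classes)) {
    tab <- table(factor(chain[partition@classes[[ci]]], levels = ids))
    if (length(unique(as.integer(tab))) != 1L)
      stop("equivalence class ", ci, " (", partition@keys$label[ci],
           " of ", partition@keys$resName[ci], " ",
           partition@keys$resSeq[ci],
           ") is unbalanced across peptides")
  }
  invisible(partition)
}

#' @describeIn buildPartition number of classes.
#' @param partition an [EquivalencePartition-class].
#' @export
nClasses <- function(partition) length(partition@classes)

setMethod("show", "EquivalencePartition", function(object) {
  sizes <- lengths(object@classes)
  cat("EquivalencePartition\n  atoms:", object@nAtoms,
      " classes:", length(object@classes),
      "\n  class sizes:", paste(names(table(sizes)), "x", table(sizes),
                                collapse = ", "), "\n")
})

#' Dump an equivalence partition as JSON (debugging aid)
#'
#' @param partition an [EquivalencePartition-class].
#' @param path optional output path.
#' @return JSON string.
#' @export
partitionJSON <- function(partition, path = NULL) {
  obj <- lapply(seq_along(partition@classes), function(i)
    list(key = as.list(partition@keys[i, ]),
         atoms = partition@classes[[i]]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
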