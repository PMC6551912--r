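# Preparation pipeline: make a raw PDB structure ready for CSM
# analysis. Mirrors the usual cleaning done before symmetry scoring:
# drop heteroatoms/solvent/hydrogens, resolve alternate locations to the
# first-listed copy, then harmonise the chains so that every peptide has
# the same (residue, atom) sequence.

SOLVENT_RESIDUES <- c("HOH", "WAT", "DOD", "SOL", "H2O")
NUCLEIC_RESIDUES <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I")

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")

#' Clean a raw structure
#'
#' Removes heteroatoms and solvent, deletes hydrogen (and deuterium)
#' atoms when requested, and resolves alternate locations by keeping the
#' first-listed copy of each atom. Chains containing nucleic-acid
#' residues are rejected: the measure is defined here for protein
#' homomers only.
#'
#' @param structure a raw [ProteinStructure-class] from [readPDB()].
#' @param removeHydrogens logical, default TRUE.
#' @param solventResidues residue names treated as solvent even when
#'   recorded as ATOM.
#' @return list with elements `structure` and `report` (a
#'   [PrepReport-class]).
#' @export
cleanStructure <- function(structure, removeHydrogens = TRUE,
                           solventResidues = SOLVENT_RESIDUES) {
  at <- structure@atoms
  if (any(at$resName %in% NUCLEIC_RESIDUES))
    stop("structure contains nucleic-acid residues (",
         paste(unique(intersect(at$resName, NUCLEIC_RESIDUES)), collapse = ", "),
         "); only protein homomers are supported")
  drop <- at$record != "ATOM" | at$resName %in% solventResidues
  nHet <- sum(drop)
  at <- at[!drop, , drop = FALSE]
  nH <- 0L
  if (removeHydrogens) {
    isH <- at$element %in% c("H", "D")
    nH <- sum(isH)
    at <- at[!isH, , drop = FALSE]
  }
  # alternate locations: keep the first-listed copy of each atom
  key <- paste(at$chainId, at$resSeq, at$iCode, at$name, sep = "|")
  dup <- duplicated(key)
  nAlt <- sum(dup)
  at <- at[!dup, , drop = FALSE]
  at$altLoc <- ""
  if (!nrow(at)) stop("structure is empty after cleaning")
  rownames(at) <- NULL
  out <- structure
  out@atoms <- at
  report <- new("PrepReport", removedHetatm = nHet, removedHydrogens = nH,
                removedAltloc = nAlt, chainsKept = unique(at$chainId))
  list(structure = out, report = report)
}

# residue-level table of one chain: ordered unique (resSeq, iCode, resName)
chainResidues <- function(at) {
  key <- paste(at$resSeq, at$iCode, sep = "|")
  first <- !duplicated(key)
  data.frame(resSeq = at$resSeq[first], iCode = at$iCode[first],
             resName = at$resName[first], key = key[first],
             stringsAsFactors = FALSE)
}

#' Harmonise the chains of a homomer
#'
#' Ensures all peptides have identical length and identical (residue
#' name, residue number, atom name) sequences: any residue position
#' missing from one or more chains is deleted from all chains, and
#' likewise for individual atoms; atoms within each residue are
#' reordered to the first chain's layout. Declared missing residues and
#' atoms (REMARK 465/470, carried by [readPDB()]) are honoured in
#' addition to direct cross-chain comparison.
#'
#' @param structure a cleaned [ProteinStructure-class] with >= 2 chains.
#' @param missingResidues optional data.frame (`resName`, `chainId`,
#'   `resSeq`) of residues declared missing; defaults to the REMARK 465
#'   table carried on the structure.
#' @param missingAtoms optional data.frame (`resName`, `chainId`,
#'   `resSeq`, `name`) of atoms declared missing; defaults to REMARK 470.
#' @return list with elements `structure` (satisfying [isPrepared()])
#'   and `report` (a [PrepReport-class]).
#' @export
harmonizeChains <- function(structure, missingResidues = NULL,
                            missingAtoms = NULL) {
  if (is.null(missingResidues)) missingResidues <- structure@remarks$missingResidues
  if (is.null(missingAtoms)) missingAtoms <- structure@remarks$missingAtoms
  at <- structure@atoms
  chains <- unique(at$chainId)
  if (length(chains) < 2L)
    stop("harmonisation needs at least two peptides")
  perChain <- lapply(chains, function(ch) at[at$chainId == ch, , drop = FALSE])
  resTabs <- lapply(perChain, chainResidues)

  # residue-name conflicts at an aligned residue position are fatal
  allKeys <- unique(unlist(lapply(resTabs, `[[`, "key")))
  for (k in allKeys) {
    names <- unique(unlist(lapply(resTabs, function(tb) tb$resName[tb$key == k])))
    if (length(names) > 1L)
      stop("chains disagree on residue identity at position ",
           sub("\\|$", "", k), ": ", paste(names, collapse = " vs "))
  }

  # residues kept: present in every chain and not declared missing anywhere
  declaredRes <- character()
  if (!is.null(missingResidues) && nrow(missingResidues))
    declaredRes <- unique(paste(missingResidues$resSeq, "", sep = "|"))
  keyLists <- lapply(resTabs, `[[`, "key")
  keepKeys <- Reduce(intersect, keyLists)
  keepKeys <- setdiff(keepKeys, declaredRes)

  prunedResidues <- data.frame(resName = character(), resSeq = integer(),
                               iCode = character(), reason = character(),
                               stringsAsFactors = FALSE)
  for (i in seq_along(resTabs)) {
    gone <- resTabs[[i]][!(resTabs[[i]]$key %in% keepKeys), , drop = FALSE]
    if (nrow(gone))
      prunedResidues <- rbind(prunedResidues,
                              data.frame(resName = gone$resName,
                                         resSeq = gone$resSeq,
                                         iCode = gone$iCode,
                                         reason = "missing from some chain",
                                         stringsAsFactors = FALSE))
  }
  prunedResidues <- unique(prunedResidues)

  resKey <- function(tb) paste(tb$resSeq, tb$iCode, sep = "|")
  perChain <- lapply(perChain, function(tb)
    tb[resKey(tb) %in% keepKeys, , drop = FALSE])

  # per-residue atom harmonisation against the first chain's layout
  declAtom <- character()
  if (!is.null(missingAtoms) && nrow(missingAtoms))
    declAtom <- unique(paste(missingAtoms$resSeq, "", missingAtoms$name, sep = "|"))
  prunedAtoms <- data.frame(chainId = character(), resSeq = integer(),
                            iCode = character(), name = character(),
                            stringsAsFactors = FALSE)
  ref <- perChain[[1]]
  refOrder <- split(seq_len(nrow(ref)), factor(resKey(ref), levels = keepKeys))
  outChains <- vector("list", length(chains))
  # atom names kept per residue: intersection across chains minus declared
  keepNames <- list()
  for (k in keepKeys) {
    nm <- Reduce(intersect, lapply(perChain, function(tb)
      tb$name[resKey(tb) == k]))
    nm <- setdiff(nm, sub("^[^|]*\\|[^|]*\\|", "", declAtom[startsWith(declAtom, paste0(k, "|"))]))
    keepNames[[k]] <- nm
  }
  for (ci in seq_along(perChain)) {
    tb <- perChain[[ci]]
    keep <- logical(nrow(tb))
    ordered <- integer(0)
    for (k in keepKeys) {
      rows <- which(resKey(tb) == k)
      nm <- keepNames[[k]]
      # reorder to the first chain's atom order within the residue
      refRows <- refOrder[[k]]
      refNames <- ref$name[refRows]
      targetNames <- refNames[refNames %in% nm]
      sel <- rows[match(targetNames, tb$name[rows])]
      dropRows <- setdiff(rows, sel)
      if (length(dropRows))
        prunedAtoms <- rbind(prunedAtoms,
                             data.frame(chainId = tb$chainId[dropRows],
                                        resSeq = tb$resSeq[dropRows],
                                        iCode = tb$iCode[dropRows],
                                        name = tb$name[dropRows],
                                        stringsAsFactors = FALSE))
      ordered <- c(ordered, sel)
    }
    outChains[[ci]] <- tb[ordered, , drop = FALSE]
  }
  at2 <- do.call(rbind, outChains)
  if (!nrow(at2)) stop("structure is empty after harmonisation")
  rownames(at2) <- NULL
  out <- structure
  out@atoms <- at2
  if (!isPrepared(out))
    stop("internal error: harmonisation failed to equalise the chains")
  lens <- lengths(peptideIndices(out))
  report <- new("PrepReport", prunedResidues = prunedResidues,
                prunedAtoms = prunedAtoms,
                finalPeptideLength = as.integer(lens[1]),
                chainsKept = unique(at2$chainId))
  list(structure = out, report = report)
}

mergeReports <- function(a, b) {
  new("PrepReport",
      removedHetatm = a@removedHetatm + b@removedHetatm,
      removedHydrogens = a@removedHydrogens + b@removedHydrogens,
      removedAltloc = a@removedAltloc + b@removedAltloc,
      prunedResidues = rbind(a@prunedResidues, b@prunedResidues),
      prunedAtoms = rbind(a@prunedAtoms, b@prunedAtoms),
      finalPeptideLength = if (is.na(b@finalPeptideLength))
        a@finalPeptideLength else b@finalPeptideLength,
      chainsKept = if (length(b@chainsKept)) b@chainsKept else a@chainsKept)
}

#' Prepare a structure for CSM analysis
#'
#' Convenience pipeline: [cleanStructure()] followed by
#' [harmonizeChains()].
#'
#' @inheritParams cleanStructure
#' @return list with elements `structure` and `report`.
#' @export
prepareStructure <- function(structure, removeHydrogens = TRUE) {
  cl <- cleanStructure(structure, removeHydrogens = removeHydrogens)
  hm <- harmonizeChains(cl$structure)
  list(structure = hm$structure, report = mergeReports(cl$report, hm$report))
}

setMethod("show", "PrepReport", function(object) {
  cat("PrepReport\n",
      " removed: ", object@removedHetatm, " het/solvent, ",
      object@removedHydrogens, " hydrogens, ",
      object@removedAltloc, " alt-loc copies\n",
      " pruned: ", nrow(object@prunedResidues), " residue positions, ",
      nrow(object@prunedAtoms), " atoms\n",
      " chains kept: ", paste(object@chainsKept, collapse = " "),
      "  peptide length: ", object@finalPeptideLength, "\n", sep = "")
})

#' Serialise a prep report to JSON
#'
#' @param report a [PrepReport-class].
#' @param path optional output path; when NULL the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
prepReportJSON <- function(report, path = NULL) {
  obj <- list(removed_hetatm = report@removedHetatm,
              removed_hydrogens = report@removedHydrogens,
              removed_altloc_atoms = report@removedAltloc,
              pruned_residues = report@prunedResidues,
              pruned_atoms = report@prunedAtoms,
              final_peptide_length = report@finalPeptideLength,
              chains_kept = report@chainsKept)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
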