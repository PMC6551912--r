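# Synthetic homomer generator with planted symmetry. One template
# peptide of pseudo-residues (real residue names, PDB-legal atom names,
# so the preparation and equivalence modules are exercised unchanged) is
# replicated around a planted axis by the powers of the group generator,
# then perturbed with isotropic Gaussian coordinate noise. Ground truth
# (axis, peptide orbit, noise level) is returned alongside.

RESIDUE_ATOMS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  GLY = c("N", "CA", "C", "O"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")
)

BRANCH_RESIDUES <- c("VAL", "LEU", "PHE", "ASP", "GLU", "ARG")
PLAIN_RESIDUES <- c("ALA", "GLY", "SER", "THR")

# template peptide: a gentle helical arc at ~12 A radius from the z
# axis, spanning a fraction of the 2*pi/l sector, with atoms jittered
# deterministically around each residue base point
buildTemplate <- function(residuesPerChain, ell, includeBranchResidues) {
  resNames <- if (includeBranchResidues)
    rep(c(PLAIN_RESIDUES, BRANCH_RESIDUES),
        length.out = residuesPerChain)
  else rep(PLAIN_RESIDUES, length.out = residuesPerChain)
  sector <- 2 * pi / ell
  rows <- list()
  for (r in seq_len(residuesPerChain)) {
    rn <- resNames[r]
    frac <- (r - 0.5) / residuesPerChain
    ang <- 0.7 * sector * frac
    radius <- 12 + 1.5 * sin(3 * frac * pi)
    base <- c(radius * cos(ang), radius * sin(ang),
              8 * (frac - 0.5))
    atoms <- RESIDUE_ATOMS[[rn]]
    off <- matrix(stats::runif(3 * length(atoms), -1.2, 1.2), ncol = 3)
    for (a in seq_along(atoms)) {
      rows[[length(rows) + 1L]] <- list(name = atoms[a], resName = rn,
                                        resSeq = r,
                                        xyz = base + off[a, ])
    }
  }
  rows
}

#' Generate a synthetic homomer with planted cyclic symmetry
#'
#' Builds l identical pseudo-peptides arranged as an exact orbit of the
#' group generator about a planted axis, adds per-coordinate Gaussian
#' noise, and optionally permutes the chain order in the file and swaps
#' the coordinates of interchangeable branch-atom pairs between
#' symmetric copies (so that name-ordered mapping is geometrically
#' wrong while the class-preserving optimum recovers it).
#'
#' Defaults emulate the crystallographic homomers the method targets:
#' chains of 20 residues (backbone plus side chains, hydrogen-free,
#' ~130 atoms per chain) at ~12 Angstrom from the axis, and noise of
#' 0.25 Angstrom per coordinate, a typical thermal displacement for
#' X-ray structures within the B-factor range the method is used on.
#'
#' @param groupOrder number of chains l (equal to the group index n).
#' @param residuesPerChain residues in the template chain (default 20).
#' @param group a [PointGroup-class]; default `pointGroup("C",
#'   groupOrder)`. For improper groups l is the operation order (2 for
#'   S1/S2).
#' @param axis planted symmetry axis (default z).
#' @param noiseSigma Gaussian noise s.d. per coordinate, Angstrom
#'   (default 0.25).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param includeBranchResidues plant Val/Leu/Phe/Asp/Glu/Arg residues
#'   with interchangeable atom pairs (default TRUE).
#' @param scrambleChainOrder permute the order chains appear in the
#'   file (default FALSE).
#' @param swapBranchLabels swap branch-pair coordinates in every second
#'   chain (default FALSE).
#' @return list with `structure` (a [ProteinStructure-class]) and
#'   `groundTruth` (list: `axis`, `chainOrbit` - chain labels in orbit
#'   order, `orbitPerm` - peptide permutation in file order, `sigma`,
#'   `group`, `seed`).
#' @export
syntheticHomomer <- function(groupOrder, residuesPerChain = 20L,
                             group = pointGroup("C", groupOrder),
                             axis = c(0, 0, 1), noiseSigma = 0.25,
                             seed = 1L, includeBranchResidues = TRUE,
                             scrambleChainOrder = FALSE,
                             swapBranchLabels = FALSE) {
  ell <- operationOrder(group)
  if (!missing(groupOrder) && groupOrder != ell && group@kind == "C")
    stop("groupOrder must equal the group order for a full planted orbit")
  axis <- unitVector(axis)
  withSeed(seed, {
    tmpl <- buildTemplate(residuesPerChain, ell, includeBranchResidues)
    M <- length(tmpl)
    xyz0 <- t(vapply(tmpl, `[[`, numeric(3), "xyz"))
    # generate in the axis frame: map the z-built template onto `axis`
    F <- orthonormalFrame(axis)
    xyz0 <- xyz0 %*% t(F[, c(1, 2, 3)])  # columns e1,e2,v: z -> axis
    op <- symmetryOperation(group, axis, c(0, 0, 0))
    chains <- vector("list", ell)
    for (k in seq_len(ell))
      chains[[k]] <- applyOperation(op, xyz0, k - 1L)
    if (swapBranchLabels) {
      for (k in seq(2L, ell, by = 2L)) {
        for (r in unique(vapply(tmpl, `[[`, numeric(1), "resSeq"))) {
          rn <- tmpl[[which(vapply(tmpl, `[[`, numeric(1), "resSeq") == r)[1]]]$resName
          for (grp in interchangeableAtoms(rn)) {
            ia <- which(vapply(tmpl, function(t)
              t$resSeq == r && t$name == grp[1], logical(1)))
            ib <- which(vapply(tmpl, function(t)
              t$resSeq == r && t$name == grp[2], logical(1)))
            tmp <- chains[[k]][ia, ]
            chains[[k]][ia, ] <- chains[[k]][ib, ]
            chains[[k]][ib, ] <- tmp
          }
        }
      }
    }
    if (noiseSigma > 0)
      for (k in seq_len(ell))
        chains[[k]] <- chains[[k]] +
          matrix(stats::rnorm(3 * M, sd = noiseSigma), ncol = 3)
    labels <- LETTERS[seq_len(ell)]
    fileOrder <- seq_len(ell)
    if (scrambleChainOrder && ell > 1L)
      fileOrder <- sample(ell)
    rows <- vector("list", ell * M)
    serial <- 0L
    for (pos in seq_len(ell)) {
      k <- fileOrder[pos]
      for (a in seq_len(M)) {
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          record = "ATOM", serial = serial, name = tmpl[[a]]$name,
          altLoc = "", resName = tmpl[[a]]$resName, chainId = labels[k],
          resSeq = tmpl[[a]]$resSeq, iCode = "",
          x = chains[[k]][a, 1], y = chains[[k]][a, 2], z = chains[[k]][a, 3],
          occupancy = 1, tempFactor = 0,
          element = substr(tmpl[[a]]$name, 1, 1), stringsAsFactors = FALSE)
      }
    }
    st <- new("ProteinStructure", atoms = do.call(rbind, rows),
              sourceId = sprintf("synthetic_%s%d_seed%d", group@kind,
                                 group@n, seed))
    # orbit: chain k (orbit index) maps under T to chain k+1
    orbitNext <- c(seq_len(ell)[-1], 1L)
    filePosOf <- match(seq_len(ell), fileOrder)   # orbit index -> file pos
    orbitPerm <- integer(ell)                     # in file-order indexing
    for (k in seq_len(ell))
      orbitPerm[filePosOf[k]] <- filePosOf[orbitNext[k]]
    gt <- list(axis = axis, chainOrbit = labels,
               orbitPerm = orbitPerm, sigma = noiseSigma,
               group = paste0(group@kind, group@n), seed = seed)
    list(structure = st, groundTruth = gt)
  })
}

#' Persist a synthetic fixture (PDB + ground-truth JSON)
#'
#' @param generated output of [syntheticHomomer()].
#' @param dir output directory (created if needed).
#' @param name base file name (default from the structure's source id).
#' @return character vector of the two paths written.
#' @export
writeFixturePDB <- function(generated, dir, name = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(name)) name <- generated$structure@sourceId
  pdbPath <- file.path(dir, paste0(name, ".pdb"))
  jsonPath <- file.path(dir, paste0(name, ".json"))
  writePDB(generated$structure, pdbPath)
  gt <- generated$groundTruth
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA), jsonPath)
  c(pdb = pdbPath, json = jsonPath)
}
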