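# Fixed-width PDB (v3.3) reading and writing, restricted to what the
# symmetry analysis needs: ATOM/HETATM coordinate records, MODEL/ENDMDL
# (first model only) and REMARK 465/470 missing-residue/atom listings.

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "SE",
                         "CL", "BR", "NA", "CD", "HG", "AS", "MO")

# Infer the element from the atom-name field when columns 77-78 are
# absent. PDB names place one-letter elements in column 14 (so the
# 4-character field starts with a blank or a digit); a non-blank,
# non-digit column 13 signals either a 4-character hydrogen name
# ("HG11") or a two-letter element ("FE1").
elementFromName <- function(rawName) {
  first <- substr(rawName, 1, 1)
  trimmed <- gsub("[ 0-9']", "", rawName)
  if (!nzchar(trimmed)) return("")
  if (first == " " || grepl("^[0-9]$", first))
    return(substr(trimmed, 1, 1))
  two <- toupper(substr(gsub("[0-9']", "", rawName), 1, 2))
  if (two %in% TWO_LETTER_ELEMENTS) return(two)
  substr(trimmed, 1, 1)
}

parseRemark465 <- function(lines) {
  out <- data.frame(resName = character(), chainId = character(),
                    resSeq = integer(), stringsAsFactors = FALSE)
  for (ln in lines) {
    toks <- strsplit(trimws(substr(ln, 11, nchar(ln))), "\\s+")[[1]]
    if (length(toks) < 3) next
    if (length(toks) == 4 && grepl("^[0-9]+$", toks[1])) toks <- toks[-1]  # model no.
    if (!grepl("^[A-Z]{1,3}$", toks[1]) || nchar(toks[2]) != 1 ||
        !grepl("^-?[0-9]+[A-Za-z]?$", toks[3])) next
    out <- rbind(out, data.frame(resName = toks[1], chainId = toks[2],
                                 resSeq = as.integer(gsub("[A-Za-z]", "", toks[3])),
                                 stringsAsFactors = FALSE))
  }
  out
}

parseRemark470 <- function(lines) {
  out <- data.frame(resName = character(), chainId = character(),
                    resSeq = integer(), name = character(),
                    stringsAsFactors = FALSE)
  for (ln in lines) {
    toks <- strsplit(trimws(substr(ln, 11, nchar(ln))), "\\s+")[[1]]
    if (length(toks) < 4) next
    if (grepl("^[0-9]+$", toks[1]) && grepl("^[A-Z]{1,3}$", toks[2])) toks <- toks[-1]
    if (!grepl("^[A-Z]{1,3}$", toks[1]) || nchar(toks[2]) != 1 ||
        !grepl("^-?[0-9]+$", toks[3])) next
    for (atm in toks[-(1:3)])
      out <- rbind(out, data.frame(resName = toks[1], chainId = toks[2],
                                   resSeq = as.integer(toks[3]), name = atm,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-width ATOM (and, optionally, HETATM) records into a
#' [ProteinStructure-class]. Multi-model files contribute only the first
#' model; ANISOU and other non-coordinate records are ignored, except
#' REMARK 465/470 missing-residue/atom listings, which are retained for
#' the preparation pipeline.
#'
#' @param path path to a PDB file.
#' @param keepHetatm logical; keep HETATM records (default FALSE). The
#'   preparation pipeline removes them in any case.
#' @return a [ProteinStructure-class].
#' @examples
#' gen <- syntheticHomomer(groupOrder = 2, residuesPerChain = 3, noiseSigma = 0)
#' f <- tempfile(fileext = ".pdb")
#' writePDB(gen$structure, f)
#' readPDB(f)
#' @export
readPDB <- function(path, keepHetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- substr(lines, 1, 6)
  wanted <- c("ATOM  ", if (keepHetatm) "HETATM")
  inModel <- 0L
  rows <- vector("list", length(lines))
  nr <- 0L
  for (i in seq_along(lines)) {
    rec <- recs[i]
    if (rec == "MODEL ") {
      inModel <- inModel + 1L
      if (inModel > 1L) break
      next
    }
    if (rec == "ENDMDL") {
      if (inModel >= 1L) break
      next
    }
    if (!rec %in% wanted) next
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record (line ", i, "): fewer than 54 columns")
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resSeq <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (is.na(serial) || anyNA(xyz) || is.na(resSeq))
      stop("malformed ATOM record (line ", i,
           "): non-numeric serial, residue number or coordinates")
    rawName <- substr(ln, 13, 16)
    elem <- trimws(substr(ln, 77, 78))
    if (!nzchar(elem) || !grepl("^[A-Za-z]+$", elem))
      elem <- elementFromName(rawName)
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    bf <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      record = trimws(rec), serial = serial, name = trimws(rawName),
      altLoc = trimws(substr(ln, 17, 17)), resName = trimws(substr(ln, 18, 20)),
      chainId = substr(ln, 22, 22), resSeq = resSeq,
      iCode = trimws(substr(ln, 27, 27)),
      x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = if (is.na(occ)) 1 else occ,
      tempFactor = if (is.na(bf)) 0 else bf,
      element = toupper(elem), stringsAsFactors = FALSE)
  }
  if (nr == 0L)
    stop("no ATOM records found in ", path)
  atoms <- do.call(rbind, rows[seq_len(nr)])
  remarks <- list()
  r465 <- lines[recs == "REMARK" & substr(lines, 8, 10) == "465"]
  r470 <- lines[recs == "REMARK" & substr(lines, 8, 10) == "470"]
  if (length(r465)) remarks$missingResidues <- parseRemark465(r465)
  if (length(r470)) remarks$missingAtoms <- parseRemark470(r470)
  new("ProteinStructure", atoms = atoms,
      sourceId = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
      remarks = remarks)
}

formatAtomName <- function(name, element) {
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 2L) return(formatC(name, width = -4))
  paste0(" ", formatC(name, width = -3))
}

#' Write a structure as a fixed-width PDB file
#'
#' Emits standard ATOM records (coordinates to 3 decimals) preserving
#' serials, names, chain identifiers and residue numbering, with a TER
#' record after each chain and END at the end of file.
#'
#' @param structure a [ProteinStructure-class]; must contain atoms.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePDB <- function(structure, path) {
  stopifnot(is(structure, "ProteinStructure"))
  at <- structure@atoms
  if (!nrow(at)) stop("cannot write an empty structure")
  con <- file(path, "w")
  on.exit(close(con))
  chain <- at$chainId[1]
  for (i in seq_len(nrow(at))) {
    if (at$chainId[i] != chain) {
      writeLines("TER", con)
      chain <- at$chainId[i]
    }
    writeLines(sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial[i] %% 100000L, formatAtomName(at$name[i], at$element[i]),
      at$altLoc[i], at$resName[i], at$chainId[i], at$resSeq[i], at$iCode[i],
      at$x[i], at$y[i], at$z[i], at$occupancy[i], at$tempFactor[i],
      formatC(at$element[i], width = 2)), con)
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}
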