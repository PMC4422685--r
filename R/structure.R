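## Structure container and PDB/FASTA I/O.
##
## A `apeh_structure` wraps a flat atom table (one row per atom, in file
## order) plus an id and a source tag. Author residue numbering is kept
## untouched; all region bounds elsewhere in the package are inclusive and
## refer to this numbering.

AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

WATER_NAMES <- c("HOH", "WAT", "DOD")

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `serial`,
#'   `name` (PDB atom name), `altloc`, `resname` (three-letter code),
#'   `chain`, `resno` (author residue number), `icode`, `x`, `y`, `z`,
#'   `occupancy`, `bfactor`, `element`.
#' @param id Label for the structure.
#' @param source Provenance string (file path or `"synthetic"`).
#' @return An object of class `apeh_structure`.
#' @export
new_structure <- function(atoms, id = "structure", source = "synthetic") {
  needed <- c("type", "serial", "name", "altloc", "resname", "chain",
              "resno", "icode", "x", "y", "z", "occupancy", "bfactor",
              "element")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (any(!nzchar(atoms$name)))
    stop("atom names must be non-empty", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(id = id, source = source, atoms = atoms),
            class = "apeh_structure")
}

is_structure <- function(x) inherits(x, "apeh_structure")

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (via bio3d) into the package's flat atom
#' table. Alternate locations other than blank or 'A' are dropped;
#' duplicated atoms within a residue (same name and altloc) are reduced to
#' the first occurrence with a warning.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param id Structure label; defaults to the file name.
#' @param chain Optional chain identifier to keep. By default all chains are
#'   read; downstream analyses assume a single-chain model.
#' @return An `apeh_structure`.
#' @export
read_structure <- function(path, id = NULL, chain = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("format error: empty PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("format error: cannot parse PDB file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("format error: no ATOM records in ", path, call. = FALSE)
  atoms <- data.frame(
    type = at$type,
    serial = as.integer(at$eleno),
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    element = if (!is.null(at$elesy)) ifelse(is.na(at$elesy), "", at$elesy) else "",
    stringsAsFactors = FALSE)
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("format error: no atoms left after filtering in ", path, call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, atoms$altloc)
  if (anyDuplicated(key)) {
    warning("duplicate atoms within a residue; keeping first occurrence",
            call. = FALSE)
    atoms <- atoms[!duplicated(key), , drop = FALSE]
  }
  new_structure(atoms, id = if (is.null(id)) basename(path) else id,
                source = path)
}

#' Write a structure to a PDB file
#'
#' @param x An `apeh_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(x, path) {
  stopifnot(is_structure(x))
  a <- x$atoms
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   insert = ifelse(nzchar(a$icode), a$icode, ""),
                   alt = ifelse(nzchar(a$altloc), a$altloc, ""),
                   o = a$occupancy, b = a$bfactor,
                   elesy = a$element)
  invisible(path)
}

## Polymer atoms used in analyses: ATOM records, waters excluded.
polymer_atoms <- function(x) {
  a <- x$atoms
  a[a$type == "ATOM" & !(a$resname %in% WATER_NAMES), , drop = FALSE]
}

## One row per residue, in order of first appearance.
residue_table <- function(x) {
  a <- polymer_atoms(x)
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resname = a$resname[first],
             key = key[first], stringsAsFactors = FALSE)
}

## Coordinates of one named atom in one residue, or NULL.
atom_xyz <- function(atoms, resno, name, chain = NULL) {
  sel <- atoms$resno == resno & atoms$name == name
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  i <- which(sel)
  if (!length(i)) return(NULL)
  as.numeric(atoms[i[1L], c("x", "y", "z")])
}

#' Extract a one-letter amino-acid sequence
#'
#' Works on a structure (residues in order, unknown three-letter codes
#' mapped to 'X'), a plain one-letter string, or a FASTA file path (first
#' record). An optional inclusive region selects by author residue number
#' for structures and by 1-based position for sequences.
#'
#' @param x `apeh_structure`, character sequence, or FASTA file path.
#' @param region Optional `c(start, end)`, inclusive.
#' @return One-letter amino-acid string.
#' @export
extract_sequence <- function(x, region = NULL) {
  if (is_structure(x)) {
    rt <- residue_table(x)
    letters1 <- unname(AA_321[rt$resname])
    letters1[is.na(letters1)] <- "X"
    numbers <- rt$resno
  } else if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) {
      fa <- bio3d::read.fasta(x)
      letters1 <- toupper(as.character(fa$ali[1L, ]))
      letters1 <- letters1[letters1 != "-"]
    } else {
      letters1 <- strsplit(toupper(x), "")[[1L]]
    }
    numbers <- seq_along(letters1)
  } else {
    stop("cannot extract a sequence from this object", call. = FALSE)
  }
  if (!is.null(region)) {
    if (length(region) != 2L || region[1L] > region[2L])
      stop("region must be c(start, end) with start <= end", call. = FALSE)
    keep <- numbers >= region[1L] & numbers <= region[2L]
    if (!any(keep) || region[1L] < min(numbers) || region[2L] > max(numbers))
      stop("range error: region [", region[1L], ",", region[2L],
           "] outside available numbering [", min(numbers), ",",
           max(numbers), "]", call. = FALSE)
    letters1 <- letters1[keep]
  }
  paste(letters1, collapse = "")
}

#' @export
print.apeh_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("apeh_structure '", x$id, "' (", x$source, ")\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms, ", nrow(rt), " polymer residues",
      if (nrow(rt)) paste0(" (", rt$resno[1L], "-", rt$resno[nrow(rt)], ")"),
      "\n", sep = "")
  invisible(x)
}
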