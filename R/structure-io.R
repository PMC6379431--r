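# Coordinate I/O. Parsing of PDB and mmCIF files is delegated to bio3d; this
# module wraps the result in a light "structure_model" container that fixes
# the conventions used everywhere else in the package: author residue
# numbering, explicit altloc/insertion handling, and ordered per-chain
# residue retrieval.

.BACKBONE <- c("N", "CA", "C", "O")
.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a structure model
#'
#' A structure model is a list with an `identifier` and an `atoms` data frame
#' with one row per atom: `chain`, `resno` (author numbering), `ins`
#' (insertion code, "" if none), `resid` (3-letter residue name), `elety`
#' (atom name), `alt` (altloc, "" if none), `occ`, `b`, `x`, `y`, `z`.
#' The atom key (chain, resno, ins, elety, alt) must be unique.
#'
#' @param identifier character label, e.g. a PDB id.
#' @param atoms data frame as described above.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(identifier, atoms) {
  required <- c("chain", "resno", "ins", "resid", "elety", "alt",
                "occ", "b", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0)
    stop("empty structure: no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$b < 0, na.rm = TRUE))
    stop("negative B-factors")
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety, atoms$alt,
               sep = "|")
  if (anyDuplicated(key))
    stop("duplicate atom key (chain, resno, ins, elety, alt): ",
         key[duplicated(key)][1])
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$ins), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("structure_model '", x$identifier, "': ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

# convert a bio3d pdb/cif object to a structure_model
.from_bio3d <- function(pdb, identifier) {
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atoms parsed")
  blank <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
  occ <- suppressWarnings(as.numeric(at$o)); occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(at$b)); b[is.na(b)] <- 0
  b[b < 0] <- 0
  atoms <- data.frame(
    chain = blank(at$chain),
    resno = as.integer(at$resno),
    ins = blank(at$insert),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    alt = blank(at$alt),
    occ = pmin(1, pmax(0, occ)),
    b = b,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    stringsAsFactors = FALSE)
  atoms$chain[atoms$chain == ""] <- "A"
  structure_model(identifier, atoms)
}

#' Read a macromolecular structure
#'
#' Reads coordinates from PDB or mmCIF (first model only, NMR-style
#' ensembles are out of scope). Altloc records are preserved; chains and
#' author residue numbers are kept exactly as deposited. Waters and
#' hydrogens are retained here and ignored by the geometry operations.
#'
#' @param path file path.
#' @param format one of "auto", "pdb", "mmcif". "auto" infers from the
#'   extension (.pdb/.ent vs .cif/.mmcif).
#' @param identifier optional label; defaults to the file base name.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(identifier))
    identifier <- tools::file_path_sans_ext(basename(path))
  .from_bio3d(pdb, identifier)
}

#' Write a structure as PDB
#'
#' Standard ATOM records via bio3d (coordinates to 3 decimals, B-factors to
#' 2 decimals). Round-trips through [read_structure()] preserve atom keys,
#' coordinates to 1e-3 Angstrom, and B-factors to 0.01.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write to '", path, "': directory does not exist")
  blank2na <- function(v) { v[v == ""] <- NA; v }
  xyz <- as.vector(t(.coords(at)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, insert = blank2na(at$ins),
                   alt = blank2na(at$alt), o = at$occ, b = at$b)
  invisible(path)
}

# polymer heavy atoms used in geometry: drop waters and hydrogens
# (standard-residue atom names starting with [digit]H are hydrogens)
.geometry_atoms <- function(atoms) {
  keep <- !(atoms$resid %in% .WATER_RESID) & !grepl("^[0-9]*H", atoms$elety)
  atoms[keep, , drop = FALSE]
}

#' Ordered C-alpha selection
#'
#' Returns one row per residue in the requested range that has a C-alpha,
#' in ascending author residue number. When a residue carries multiple
#' altloc C-alphas the highest-occupancy conformer is taken (ties broken
#' lexicographically by altloc). Residues in the range without a C-alpha
#' are omitted and reported in the `missing_residues` attribute.
#' Insertion codes must be absent within the range (claudin author
#' numbering has none; ranges with insertions are ambiguous).
#'
#' @param model a [structure_model()].
#' @param chain chain identifier.
#' @param residue_range inclusive integer interval `c(lo, hi)`.
#' @return data frame with columns `resno`, `x`, `y`, `z`; attribute
#'   `missing_residues` lists range residues without a C-alpha.
#' @export
select_calpha <- function(model, chain, residue_range) {
  stopifnot(inherits(model, "structure_model"))
  if (!(chain %in% model$atoms$chain))
    stop("unknown chain '", chain, "' (have: ",
         paste(sort(unique(model$atoms$chain)), collapse = ", "), ")")
  lo <- min(residue_range); hi <- max(residue_range)
  at <- .geometry_atoms(model$atoms)
  at <- at[at$chain == chain & at$resno >= lo & at$resno <= hi, , drop = FALSE]
  if (any(at$ins != ""))
    stop("insertion codes present in range ", lo, "-", hi,
         " of chain ", chain, "; geometry ranges must be insertion-free")
  ca <- at[at$elety == "CA" & !(at$resid %in% c("CA")), , drop = FALSE]
  if (nrow(ca) == 0)
    stop("empty C-alpha selection: chain ", chain, ", residues ", lo, "-", hi)
  # altloc resolution: highest occupancy, tie -> lexicographically first
  ca <- ca[order(ca$resno, -ca$occ, ca$alt), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out <- data.frame(resno = ca$resno, x = ca$x, y = ca$y, z = ca$z)
  attr(out, "missing_residues") <- setdiff(lo:hi, out$resno)
  out
}
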