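# Amino-acid composition at an alignment column mapped from a reference
# residue, e.g. the distribution of helix-breaking residues at the
# position that controls transmembrane-helix bending across a protein
# family.

#' Composition of the alignment column holding a reference residue
#'
#' Maps residue `reference_residue` (1-based in the ungapped reference
#' sequence, i.e. author numbering) through the reference's gaps to an
#' alignment column and reports the amino-acid composition of that column
#' over all sequences. '-' and '.' are gaps and are counted separately;
#' letters are case-insensitive.
#'
#' @param alignment path to an aligned FASTA file, a named character
#'   vector of equal-length gapped sequences, or a Biostrings XStringSet.
#' @param reference_id name of the reference sequence.
#' @param reference_residue residue number within the ungapped reference.
#' @return object of class `alignment_column_report`: `composition`
#'   (named fractions over non-gap symbols, descending), `column`
#'   (1-based alignment column), `n_sequences`, `gap_fraction`, `counts`.
#' @export
column_composition <- function(alignment, reference_id, reference_residue) {
  seqs <- .load_alignment(alignment)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in alignment: ",
         names(seqs)[duplicated(names(seqs))][1])
  if (!(reference_id %in% names(seqs)))
    stop("reference sequence '", reference_id, "' not in alignment")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("sequences have unequal lengths; not an alignment")
  ref <- toupper(strsplit(seqs[[reference_id]], "")[[1]])
  is_gap <- ref %in% c("-", ".")
  ungapped <- which(!is_gap)
  if (reference_residue < 1 || reference_residue > length(ungapped))
    stop("reference residue ", reference_residue,
         " is beyond the ungapped reference length (", length(ungapped), ")")
  col <- ungapped[reference_residue]
  chars <- toupper(vapply(seqs, function(s) substr(s, col, col), character(1)))
  gap <- chars %in% c("-", ".")
  counts <- table(chars[!gap])
  comp <- sort(as.numeric(counts) / sum(counts), decreasing = TRUE)
  names(comp) <- names(sort(counts, decreasing = TRUE))
  structure(list(reference_id = reference_id,
                 reference_residue = as.integer(reference_residue),
                 column = as.integer(col),
                 composition = comp,
                 counts = counts,
                 n_sequences = length(seqs),
                 n_gap = sum(gap),
                 gap_fraction = mean(gap)),
            class = "alignment_column_report")
}

.load_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    ss <- Biostrings::readAAStringSet(alignment)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))  # id = first token of header
    return(out)
  }
  if (inherits(alignment, "XStringSet")) {
    out <- as.character(alignment)
    names(out) <- sub("\\s.*$", "", names(alignment))
    return(out)
  }
  if (is.character(alignment) && !is.null(names(alignment)))
    return(alignment)
  stop("alignment must be a FASTA path, a named character vector, ",
       "or an XStringSet")
}

#' @export
print.alignment_column_report <- function(x, ...) {
  cat(sprintf("alignment column %d (residue %d of %s), %d sequences:\n",
              x$column, x$reference_residue, x$reference_id, x$n_sequences))
  for (aa in names(x$composition))
    cat(sprintf("  %s: %.1f%%\n", aa, 100 * x$composition[[aa]]))
  if (x$n_gap > 0)
    cat(sprintf("  gaps: %d (%.1f%%)\n", x$n_gap, 100 * x$gap_fraction))
  invisible(x)
}
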