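# FASTA input/output (Biostrings-backed) with the package's normalization
# rules: U mapped to T, case folded to upper, duplicate ids rejected,
# ambiguity codes other than N rejected.

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @param allow_gaps logical; permit `-` characters (aligned FASTA).
#' @return named character vector of upper-case DNA sequences, in file order.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[[i]], allow_gap = allow_gaps,
                   what = paste0("FASTA record '", ids[i], "'"))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
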