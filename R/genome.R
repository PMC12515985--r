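#' Construct an annotated mitogenome record
#'
#' Container for an annotated (possibly circular) mitochondrial genome: the
#' deposited-strand sequence plus an ordered feature table. Coordinates are
#' 1-based inclusive throughout, matching the GenBank convention; the strand
#' of the deposited sequence is treated as the heavy (H) strand.
#'
#' @param sequence deposited-strand DNA as a single string over A/C/G/T/N.
#' @param features data.frame with columns `gene` (canonical label or the raw
#'   label for unknowns), `category` (`PCG`/`tRNA`/`rRNA`/`other`), `strand`
#'   (`H` = deposited strand, `L` = its complement), `codon_table` (integer),
#'   `label_raw`, and a list-column `intervals` of two-column integer matrices
#'   (`start`, `end`, 1-based inclusive, in transcription order; multiple rows
#'   only for origin-spanning features on circular genomes).
#' @param accession,organism record identifiers.
#' @param topology `"circular"` or `"linear"`.
#' @return object of class `mito_genome`.
#' @export
mito_genome <- function(sequence, features,
                        accession = "unknown", organism = "unknown",
                        topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is_string(sequence), nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  check_alphabet(sequence, what = "genome sequence")
  features <- validate_features(features, nchar(sequence))
  structure(
    list(accession = accession, organism = organism,
         sequence = sequence, topology = topology, features = features),
    class = "mito_genome"
  )
}

validate_features <- function(features, seqlen) {
  needed <- c("gene", "category", "strand", "codon_table", "label_raw",
              "intervals")
  stopifnot(is.data.frame(features), all(needed %in% names(features)))
  stopifnot(all(features$category %in% c("PCG", "tRNA", "rRNA", "other")),
            all(features$strand %in% c("H", "L")))
  for (i in seq_len(nrow(features))) {
    iv <- features$intervals[[i]]
    if (!is.matrix(iv) || ncol(iv) != 2L || nrow(iv) < 1L) {
      stop("feature ", features$gene[i], ": intervals must be a 2-column ",
           "matrix with at least one row", call. = FALSE)
    }
    if (any(iv[, 1] < 1L) || any(iv[, 2] > seqlen) || any(iv[, 1] > iv[, 2])) {
      stop("feature ", features$gene[i], " lies outside sequence bounds ",
           "[1, ", seqlen, "]", call. = FALSE)
    }
  }
  rownames(features) <- NULL
  features
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s), %s, %d bp, %d features\n",
              x$accession, x$organism, x$topology, nchar(x$sequence),
              nrow(x$features)))
  tab <- table(factor(x$features$category,
                      levels = c("PCG", "tRNA", "rRNA", "other")))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Flat feature table of a genome
#'
#' One row per feature with its genomic span, suitable for TSV export.
#' Origin-spanning features report the start of their first interval and the
#' end of their last; `length` is the summed interval length.
#'
#' @param genome a [mito_genome].
#' @return data.frame with columns accession, gene, category, strand, start,
#'   end, length, n_intervals.
#' @export
feature_table <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  data.frame(
    accession = genome$accession,
    gene = f$gene,
    category = f$category,
    strand = f$strand,
    start = vapply(f$intervals, function(iv) iv[1L, 1L], numeric(1)),
    end = vapply(f$intervals, function(iv) iv[nrow(iv), 2L], numeric(1)),
    length = vapply(f$intervals,
                    function(iv) sum(iv[, 2] - iv[, 1] + 1), numeric(1)),
    n_intervals = vapply(f$intervals, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
}

# extract the (strand-corrected) nucleotide sequence of one feature row
feature_sequence <- function(genome, i) {
  iv <- genome$features$intervals[[i]]
  parts <- substring(genome$sequence, iv[, 1], iv[, 2])
  s <- paste(parts, collapse = "")
  if (genome$features$strand[i] == "L") s <- revcomp(s)
  s
}
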