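# Strand-corrected, in-frame protein-coding sequences with start/stop
# metadata. Mitochondrial PCGs frequently end on an incomplete stop codon
# (T- or TA-) completed by post-transcriptional polyadenylation; the stop
# kind is classified from the tail length modulo 3.

new_coding_seq <- function(gene, nt, start_codon, stop_kind, stop_codon,
                           trimmed_nt) {
  structure(
    list(gene = gene, nt = nt, start_codon = start_codon,
         stop_kind = stop_kind, stop_codon = stop_codon,
         trimmed_nt = trimmed_nt),
    class = "coding_seq"
  )
}

#' @export
print.coding_seq <- function(x, ...) {
  cat(sprintf("<coding_seq> %s: %d nt, start %s, stop %s (%s)\n",
              x$gene, nchar(x$nt), x$start_codon, x$stop_codon, x$stop_kind))
  invisible(x)
}

#' Extract a strand-corrected coding sequence from a genome
#'
#' Concatenates the feature's intervals in transcription order,
#' reverse-complements L-strand features, classifies the stop codon from the
#' sequence tail and strips it: a final TAA/TAG is a complete stop, a trailing
#' TA (length 2 mod 3) or T (length 1 mod 3) is an incomplete stop. The
#' trimmed sequence (`trimmed_nt`) is in frame, stop-free, and is the unit of
#' all downstream codon counting.
#'
#' @param genome a [mito_genome].
#' @param feature row index into `genome$features`, or a canonical gene label.
#' @param code a [genetic_code] used for the internal-stop frame check.
#' @return a `coding_seq`: list with `gene`, `nt`, `start_codon`,
#'   `stop_kind` (`complete`/`incomplete_T`/`incomplete_TA`/`none`),
#'   `stop_codon` and `trimmed_nt`.
#' @export
extract_coding_seq <- function(genome, feature, code = genetic_code(5)) {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.character(feature)) {
    idx <- which(genome$features$gene == feature)
    if (length(idx) == 0L) {
      stop("no feature labelled '", feature, "'", call. = FALSE)
    }
    feature <- idx[1]
  }
  if (genome$features$category[feature] != "PCG") {
    stop("feature ", genome$features$gene[feature], " is not a PCG",
         call. = FALSE)
  }
  nt <- feature_sequence(genome, feature)
  classify_coding_seq(nt, gene = genome$features$gene[feature], code = code)
}

# classify start/stop and trim; shared by extraction and the simulator
classify_coding_seq <- function(nt, gene = "PCG", code = genetic_code(5)) {
  n <- nchar(nt)
  if (n < 6L) {
    stop("coding sequence for ", gene, " is too short (", n, " nt)",
         call. = FALSE)
  }
  rem <- n %% 3L
  if (rem == 1L && substr(nt, n, n) == "T") {
    stop_kind <- "incomplete_T"; stop_codon <- "T"
    trimmed <- substr(nt, 1L, n - 1L)
  } else if (rem == 2L && substr(nt, n - 1L, n) == "TA") {
    stop_kind <- "incomplete_TA"; stop_codon <- "TA"
    trimmed <- substr(nt, 1L, n - 2L)
  } else if (rem == 0L && substr(nt, n - 2L, n) %in% code$stops) {
    stop_kind <- "complete"; stop_codon <- substr(nt, n - 2L, n)
    trimmed <- substr(nt, 1L, n - 3L)
  } else if (rem == 0L) {
    warning("coding sequence for ", gene,
            " does not end in a stop codon or incomplete tail")
    stop_kind <- "none"; stop_codon <- ""
    trimmed <- nt
  } else {
    stop("coding sequence for ", gene, " has length ", n,
         " (", rem, " mod 3) with no recognizable incomplete stop tail",
         call. = FALSE)
  }
  cods <- codons_of(trimmed)
  internal_stop <- which(cods %in% code$stops)
  if (length(internal_stop) > 0L) {
    stop("frame error in ", gene, ": internal stop codon ",
         cods[internal_stop[1]], " at codon ", internal_stop[1],
         call. = FALSE)
  }
  new_coding_seq(gene, nt, substr(nt, 1L, 3L), stop_kind, stop_codon, trimmed)
}

#' Concatenate a strand-corrected gene set
#'
#' Joins the strand-corrected sequences of the selected features in genome
#' order (by first-interval start). Overlapping genes are each counted in
#' full, i.e. shared nucleotides appear once per feature.
#'
#' @param genome a [mito_genome].
#' @param category optional category filter (`PCG`, `tRNA`, `rRNA`).
#' @param genes optional vector of canonical gene labels (overrides
#'   `category`).
#' @return list with `sequence`, `length`, `n_features`, `genes`.
#' @export
concat_gene_set <- function(genome, category = NULL, genes = NULL) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  idx <- if (!is.null(genes)) {
    which(f$gene %in% genes)
  } else if (!is.null(category)) {
    which(f$category == category)
  } else {
    stop("supply either `category` or `genes`", call. = FALSE)
  }
  if (length(idx) == 0L) {
    stop("no features match the requested gene set", call. = FALSE)
  }
  starts <- vapply(f$intervals[idx], function(iv) iv[1L, 1L], numeric(1))
  idx <- idx[order(starts)]
  seqs <- vapply(idx, function(i) feature_sequence(genome, i), character(1))
  seq <- paste(seqs, collapse = "")
  list(sequence = seq, length = nchar(seq), n_features = length(idx),
       genes = f$gene[idx])
}

#' All coding sequences of a genome
#'
#' @param genome a [mito_genome].
#' @param code a [genetic_code].
#' @return named list of `coding_seq` objects in genome order.
#' @export
coding_seqs <- function(genome, code = genetic_code(5)) {
  f <- genome$features
  idx <- which(f$category == "PCG")
  if (length(idx) == 0L) stop("genome has no PCG features", call. = FALSE)
  starts <- vapply(f$intervals[idx], function(iv) iv[1L, 1L], numeric(1))
  idx <- idx[order(starts)]
  out <- lapply(idx, function(i) extract_coding_seq(genome, i, code))
  names(out) <- f$gene[idx]
  out
}
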