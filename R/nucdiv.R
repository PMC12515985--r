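# Nucleotide diversity (pi): the mean, over all unordered sequence pairs in
# an alignment, of (pairwise differences / pairwise compared sites). Default
# site handling is pairwise deletion — a column counts for a pair only when
# both rows carry an unambiguous A/C/G/T there; complete deletion (columns
# where every row is A/C/G/T) is available as an alternative mode.

#' Construct a multi-species alignment
#'
#' @param seqs named character vector (or list) of equal-length aligned
#'   sequences over A/C/G/T/N/-.
#' @param partitions optional data.frame `gene, start, end` (1-based
#'   inclusive alignment columns; several rows per gene allowed,
#'   non-overlapping within a gene).
#' @return object of class `multi_alignment`: list with `taxa`, `seqs`,
#'   `mat` (character matrix taxa x columns), `n_columns`, `partitions`.
#' @export
multi_alignment <- function(seqs, partitions = NULL) {
  seqs <- unlist(seqs)
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[[i]], allow_gap = TRUE,
                   what = paste0("alignment row '", names(seqs)[i], "'"))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  if (!is.null(partitions)) {
    stopifnot(is.data.frame(partitions),
              all(c("gene", "start", "end") %in% names(partitions)))
    if (any(partitions$start < 1L) || any(partitions$end > lens[1]) ||
        any(partitions$start > partitions$end)) {
      stop("partition ranges outside alignment bounds [1, ", lens[1], "]",
           call. = FALSE)
    }
    for (d in split(partitions, partitions$gene)) {
      cols <- unlist(Map(seq.int, d$start, d$end))
      if (anyDuplicated(cols)) {
        stop("overlapping partition ranges for gene ", d$gene[1],
             call. = FALSE)
      }
    }
  }
  structure(
    list(taxa = names(seqs), seqs = seqs, mat = mat,
         n_columns = unname(lens[1]), partitions = partitions),
    class = "multi_alignment"
  )
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("<multi_alignment> %d taxa x %d columns, %s partitions\n",
              length(x$taxa), x$n_columns,
              if (is.null(x$partitions)) "no" else
                length(unique(x$partitions$gene))))
  invisible(x)
}

#' Nucleotide diversity over alignment columns
#'
#' @param aln a [multi_alignment].
#' @param columns integer vector of alignment columns to evaluate (default:
#'   all).
#' @param deletion `"pairwise"` (default): a column is compared for a pair
#'   when both rows are A/C/G/T there; `"complete"`: only columns where every
#'   row is A/C/G/T are used at all.
#' @return list with `pi`, `n_sites_used` (columns with at least one
#'   comparable pair), `n_pairs_used`. Errors when no pair has any comparable
#'   site.
#' @export
nucleotide_diversity <- function(aln, columns = NULL,
                                 deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "multi_alignment"))
  if (is.null(columns)) columns <- seq_len(aln$n_columns)
  if (length(columns) == 0L) stop("no columns to evaluate", call. = FALSE)
  m <- aln$mat[, columns, drop = FALSE]
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  if (deletion == "complete") {
    keep <- colSums(ok) == nrow(m)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
    if (ncol(m) == 0L) {
      stop("pi undefined: no columns survive complete deletion",
           call. = FALSE)
    }
  }
  nr <- nrow(m)
  ratios <- numeric(0)
  any_pair <- rep(FALSE, ncol(m))
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) next
      any_pair <- any_pair | comp
      ratios <- c(ratios, sum(m[i, comp] != m[j, comp]) / nc)
    }
  }
  n_pairs_total <- nr * (nr - 1L) / 2L
  if (length(ratios) == 0L) {
    stop("pi undefined: no sequence pair shares a comparable site",
         call. = FALSE)
  }
  if (length(ratios) < n_pairs_total) {
    warning(n_pairs_total - length(ratios),
            " sequence pair(s) share no comparable site and were dropped")
  }
  list(pi = mean(ratios), n_sites_used = sum(any_pair),
       n_pairs_used = length(ratios))
}

#' Sliding-window nucleotide diversity
#'
#' Windows are anchored at column 1 and advance by `step`; only full-length
#' windows are evaluated (trailing partial windows dropped). If the window is
#' longer than the alignment, a single truncated window is returned with a
#' warning.
#'
#' @param aln a [multi_alignment].
#' @param window,step window length and step in alignment columns (defaults
#'   200 and 20); `window >= step >= 1`.
#' @param deletion passed to [nucleotide_diversity()].
#' @return data.frame with columns start, end (1-based inclusive),
#'   n_sites_used, pi.
#' @export
sliding_window_pi <- function(aln, window = 200L, step = 20L,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "multi_alignment"))
  if (!(window >= step && step >= 1L)) {
    stop("need window >= step >= 1", call. = FALSE)
  }
  len <- aln$n_columns
  if (window > len) {
    warning("window (", window, ") exceeds alignment length (", len,
            "); returning one truncated window")
    starts <- 1L
    window <- len
  } else {
    starts <- seq.int(1L, len - window + 1L, by = step)
  }
  rows <- lapply(starts, function(s) {
    res <- nucleotide_diversity(aln, columns = s:(s + window - 1L),
                                deletion = deletion)
    data.frame(start = s, end = s + window - 1L,
               n_sites_used = res$n_sites_used, pi = res$pi)
  })
  do.call(rbind, rows)
}

#' Per-partition (per-gene) nucleotide diversity
#'
#' @param aln a [multi_alignment] with `partitions` set.
#' @param deletion passed to [nucleotide_diversity()].
#' @return data.frame with gene, n_columns, n_sites_used, pi, ordered as the
#'   partition table; attributes `argmax` and `argmin` name the most and
#'   least diverse genes.
#' @export
per_partition_pi <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "multi_alignment"))
  if (is.null(aln$partitions)) {
    stop("alignment has no partition table", call. = FALSE)
  }
  genes <- unique(aln$partitions$gene)
  rows <- list()
  for (g in genes) {
    d <- aln$partitions[aln$partitions$gene == g, ]
    cols <- unlist(Map(seq.int, d$start, d$end))
    if (length(cols) == 0L) {
      warning("empty partition for gene ", g, "; skipped")
      next
    }
    res <- nucleotide_diversity(aln, columns = cols, deletion = deletion)
    rows[[g]] <- data.frame(gene = g, n_columns = length(cols),
                            n_sites_used = res$n_sites_used, pi = res$pi,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "argmax") <- out$gene[which.max(out$pi)]
  attr(out, "argmin") <- out$gene[which.min(out$pi)]
  out
}

#' Read an aligned FASTA plus partition table
#'
#' The partition TSV has columns `gene`, `start`, `end` in 1-based inclusive
#' alignment coordinates, matching the internal convention.
#'
#' @param fasta_path aligned FASTA path.
#' @param partition_path optional partition TSV path.
#' @return a [multi_alignment].
#' @export
read_alignment <- function(fasta_path, partition_path = NULL) {
  seqs <- read_fasta(fasta_path, allow_gaps = TRUE)
  partitions <- NULL
  if (!is.null(partition_path)) {
    partitions <- read.delim(partition_path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "start", "end") %in% names(partitions)))
  }
  multi_alignment(seqs, partitions)
}
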