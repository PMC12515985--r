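# Base composition, AT/GC content and strand skews, and positional
# (codon-site) composition. All statistics are defined over A/C/G/T only;
# N (and any gap) is excluded from numerator and denominator alike.
# Skew conventions: AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C),
# computed on the deposited (H) strand as given.

#' Base composition and strand skews of a sequence
#'
#' @param seq DNA string over A/C/G/T/N (gaps tolerated and excluded).
#' @return object of class `base_composition`: list with `counts` (named
#'   A/C/G/T), `n_excluded`, `at_content`, `gc_content`, `at_skew`,
#'   `gc_skew`. A skew whose denominator is zero is `NA` (undefined), not 0.
#' @examples
#' base_composition("AAAT")$at_skew   # (3-1)/4 = 0.5
#' @export
base_composition <- function(seq) {
  stopifnot(is_string(seq))
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  b <- chars(toupper(seq))
  counts <- c(A = sum(b == "A"), C = sum(b == "C"),
              G = sum(b == "G"), T = sum(b == "T"))
  n <- sum(counts)
  if (n == 0L) stop("sequence has no A/C/G/T bases", call. = FALSE)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(
    list(
      counts = counts,
      n_excluded = length(b) - n,
      at_content = at / n,
      gc_content = gc / n,
      at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
      gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
    ),
    class = "base_composition"
  )
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf(
    "<base_composition> n=%d (excl %d)  AT%%=%.4f  AT-skew=%s  GC-skew=%s\n",
    sum(x$counts), x$n_excluded, x$at_content,
    format(round(x$at_skew, 4)), format(round(x$gc_skew, 4))))
  invisible(x)
}

#' Codon-position composition of a coding sequence
#'
#' Base counts at each of the three codon positions, computed over the
#' trimmed (stop-free, in-frame) sequence; all sense codons contribute.
#' A3/T3/C3/G3 are the third-position counts; GC1/GC2/GC3 are the G+C
#' fractions at each position and GC12 is the arithmetic mean of GC1 and GC2.
#'
#' @param x a `coding_seq` (its `trimmed_nt` is used) or an in-frame DNA
#'   string whose length is a multiple of 3.
#' @return object of class `positional_composition`: list with `counts`
#'   (3 x 4 matrix, rows = codon positions, columns A/C/G/T), `n_codons`,
#'   `gc1`, `gc2`, `gc3`, `gc12`.
#' @export
positional_composition <- function(x) {
  nt <- if (inherits(x, "coding_seq")) x$trimmed_nt else x
  stopifnot(is_string(nt))
  cods <- codons_of(nt)
  if (length(cods) == 0L) stop("zero codons", call. = FALSE)
  m <- matrix(unlist(strsplit(cods, "")), ncol = 3L, byrow = TRUE)
  counts <- t(vapply(1:3, function(p) {
    c(A = sum(m[, p] == "A"), C = sum(m[, p] == "C"),
      G = sum(m[, p] == "G"), T = sum(m[, p] == "T"))
  }, numeric(4)))
  rownames(counts) <- paste0("p", 1:3)
  gc_at <- function(p) {
    tot <- sum(counts[p, ])
    if (tot == 0) NA_real_ else (counts[p, "G"] + counts[p, "C"]) / tot
  }
  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)
  structure(
    list(counts = counts, n_codons = length(cods),
         gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2),
    class = "positional_composition"
  )
}

#' @export
print.positional_composition <- function(x, ...) {
  cat(sprintf(
    "<positional_composition> %d codons  GC1=%.4f GC2=%.4f GC3=%.4f GC12=%.4f\n",
    x$n_codons, x$gc1, x$gc2, x$gc3, x$gc12))
  invisible(x)
}

#' Per-dataset composition table of an annotated genome
#'
#' One row per dataset — the whole deposited strand, the strand-corrected
#' concatenated PCGs, tRNAs and rRNAs — with length, base percentages and
#' skews. A dataset whose category is absent from the annotation is omitted
#' with a warning.
#'
#' @param genome a [mito_genome].
#' @return data.frame with columns accession, dataset, length, pct_A, pct_T,
#'   pct_G, pct_C, pct_AT, at_skew, gc_skew (full precision; round at
#'   reporting time).
#' @export
dataset_composition <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  sets <- list(whole = genome$sequence)
  for (cat_ in c("PCG", "tRNA", "rRNA")) {
    if (any(genome$features$category == cat_)) {
      sets[[paste0(cat_, "s")]] <- concat_gene_set(genome, cat_)$sequence
    } else {
      warning("no ", cat_, " features; dataset row omitted")
    }
  }
  rows <- lapply(names(sets), function(nm) {
    bc <- base_composition(sets[[nm]])
    n <- sum(bc$counts)
    data.frame(
      accession = genome$accession, dataset = nm,
      length = nchar(sets[[nm]]),
      pct_A = 100 * bc$counts[["A"]] / n, pct_T = 100 * bc$counts[["T"]] / n,
      pct_G = 100 * bc$counts[["G"]] / n, pct_C = 100 * bc$counts[["C"]] / n,
      pct_AT = 100 * bc$at_content,
      at_skew = bc$at_skew, gc_skew = bc$gc_skew,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
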