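# Codon counting, relative synonymous codon usage (RSCU) and the start/stop
# codon census. RSCU compares each codon's observed count with the count
# expected if its synonymous family were used uniformly:
#   RSCU(c) = count(c) / (family_total / family_size),
# so 1 marks unbiased usage and family RSCU values always sum to the family
# size. Stop codons are excluded from the RSCU universe (62 sense codons
# under the invertebrate mitochondrial code) and censused separately.

#' Count codons over a set of coding sequences
#'
#' Counts are taken over each sequence's trimmed, in-frame `trimmed_nt`
#' (stop codons and incomplete tails excluded); the start codon is counted
#' as its literal codon. Per-gene tables are summable to a per-species table.
#'
#' @param cds_list list of `coding_seq` objects (or in-frame DNA strings).
#' @param code a [genetic_code].
#' @param label label for the resulting table (species or gene set).
#' @return object of class `codon_counts`: list with `label`, `counts`
#'   (named integer vector over all 64 codons) and `n_sense`.
#' @export
count_codons <- function(cds_list, code = genetic_code(5), label = "") {
  if (inherits(cds_list, "coding_seq") || is_string(cds_list)) {
    cds_list <- list(cds_list)
  }
  stopifnot(length(cds_list) > 0L)
  all_codons <- names(code$map)
  counts <- setNames(integer(64L), all_codons)
  for (cds in cds_list) {
    nt <- if (inherits(cds, "coding_seq")) cds$trimmed_nt else cds
    cods <- codons_of(nt)
    cods <- cods[cods %in% all_codons]  # codons containing N are skipped
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(
    list(label = label, counts = counts,
         n_sense = sum(counts[code$sense])),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %s: %d sense codons\n",
              if (nzchar(x$label)) x$label else "(unlabelled)", x$n_sense))
  invisible(x)
}

# add two codon count tables
#' @export
`+.codon_counts` <- function(e1, e2) {
  structure(
    list(label = paste(e1$label, e2$label, sep = "+"),
         counts = e1$counts + e2$counts,
         n_sense = e1$n_sense + e2$n_sense),
    class = "codon_counts"
  )
}

#' Relative synonymous codon usage
#'
#' @param counts a `codon_counts` table (from [count_codons()]).
#' @param code a [genetic_code].
#' @return data.frame with one row per sense codon: `codon`, `amino_acid`,
#'   `count`, `family_size`, `rscu`. When a whole family is unobserved its
#'   members get `rscu = NA` (undefined).
#' @examples
#' code <- genetic_code(5)
#' cc <- count_codons(c("AAAAAAAAAAAG"), code)  # Lys 3:1
#' compute_rscu(cc, code)[c("AAA", "AAG"), "rscu"]  # 1.5, 0.5
#' @export
compute_rscu <- function(counts, code = genetic_code(5)) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_sense <= 0L) {
    stop("no sense codons counted; RSCU undefined", call. = FALSE)
  }
  codon <- code$sense
  aa <- unname(code$map[codon])
  cnt <- unname(counts$counts[codon])
  fam_total <- tapply(cnt, aa, sum)[aa]
  size <- unname(code$family_size[codon])
  rscu <- ifelse(fam_total > 0, cnt * size / fam_total, NA_real_)
  out <- data.frame(codon = codon, amino_acid = aa, count = cnt,
                    family_size = size, rscu = unname(rscu),
                    stringsAsFactors = FALSE)
  rownames(out) <- codon
  out
}

#' Classify RSCU values into bias classes
#'
#' Strict thresholds: `rscu > hi` is overrepresented, `rscu < lo` is
#' underrepresented, values in `[lo, hi]` are unbiased; `NA` RSCU (whole
#' family unobserved) is `undefined`.
#'
#' @param entries data.frame from [compute_rscu()].
#' @param hi,lo classification thresholds, `hi > lo > 0`; defaults 1.6 / 0.6.
#' @return `entries` with a `bias_class` column added.
#' @export
classify_rscu <- function(entries, hi = 1.6, lo = 0.6) {
  if (!(is.numeric(hi) && is.numeric(lo) && hi > lo && lo > 0)) {
    stop("invalid thresholds: need hi > lo > 0", call. = FALSE)
  }
  stopifnot(is.data.frame(entries), "rscu" %in% names(entries))
  entries$bias_class <- ifelse(
    is.na(entries$rscu), "undefined",
    ifelse(entries$rscu > hi, "overrepresented",
           ifelse(entries$rscu < lo, "underrepresented", "unbiased")))
  entries
}

#' Pool RSCU across species
#'
#' Two pooling semantics, labelled distinctly: `"mean"` averages the
#' per-species RSCU vectors (each species weighted equally, undefined values
#' dropped per codon); `"pooled"` sums the count tables first and computes
#' RSCU of the summed counts. These generally differ.
#'
#' @param counts_list list of `codon_counts`, one per species.
#' @param code a [genetic_code].
#' @param mode `"mean"` or `"pooled"`.
#' @return data.frame as [compute_rscu()], plus a `mode` column; in mean
#'   mode `count` is the mean per-species count.
#' @export
rscu_pool <- function(counts_list, code = genetic_code(5),
                      mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(counts_list) > 0L)
  if (mode == "pooled") {
    tot <- Reduce(`+`, counts_list)
    out <- compute_rscu(tot, code)
    out$count <- out$count / length(counts_list)  # mean count per species
  } else {
    per <- lapply(counts_list, compute_rscu, code = code)
    rscu_mat <- vapply(per, `[[`, numeric(nrow(per[[1]])), "rscu")
    cnt_mat <- vapply(per, `[[`, numeric(nrow(per[[1]])), "count")
    out <- per[[1]]
    out$rscu <- rowMeans(rscu_mat, na.rm = TRUE)
    out$rscu[!is.finite(out$rscu)] <- NA_real_
    out$count <- rowMeans(cnt_mat)
  }
  out$mode <- mode
  out
}

#' Start and stop codon census
#'
#' Bins start codons by their literal 3-mer and stops by kind: complete TAA
#' or TAG, incomplete `T-`, incomplete `TA-`.
#'
#' @param cds_list list of `coding_seq` objects.
#' @return list with `starts` and `stops`, each a named integer vector.
#' @export
start_stop_census <- function(cds_list) {
  stopifnot(length(cds_list) > 0L)
  starts <- vapply(cds_list, `[[`, "", "start_codon")
  stop_lab <- vapply(cds_list, function(cds) {
    switch(cds$stop_kind,
           complete = cds$stop_codon,
           incomplete_T = "T-",
           incomplete_TA = "TA-",
           none = "none")
  }, "")
  list(
    starts = c(table(starts)),
    stops = c(table(stop_lab))
  )
}
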