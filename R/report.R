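# Run configuration and the combined per-genome / per-cohort report.
# The analysis drivers under analysis/ are thin wrappers over these.

#' Analysis run configuration
#'
#' Central defaults for the whole chain. All values are overridable; the
#' defaults are the conventional ones for mitogenome codon-usage work:
#' invertebrate mitochondrial code (table 5), RSCU bias thresholds 1.6/0.6,
#' 200-nt windows advancing by 20 nt for sliding-window diversity (100/20 is
#' a common alternative), neutrality classification at alpha 0.05 with slope
#' cut 0.5, pairwise-deletion site handling.
#'
#' @param genetic_code_id NCBI translation table id.
#' @param rscu_hi,rscu_lo RSCU bias thresholds.
#' @param window,step sliding-window parameters (nt); `window >= step >= 1`.
#' @param alpha,slope_cut neutrality classification parameters.
#' @param pi_deletion `"pairwise"` or `"complete"`.
#' @param seed optional RNG seed echoed into outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(genetic_code_id = 5L, rscu_hi = 1.6, rscu_lo = 0.6,
                       window = 200L, step = 20L, alpha = 0.05,
                       slope_cut = 0.5,
                       pi_deletion = c("pairwise", "complete"),
                       seed = NULL) {
  pi_deletion <- match.arg(pi_deletion)
  if (!(rscu_hi > rscu_lo && rscu_lo > 0)) {
    stop("invalid RSCU thresholds: need hi > lo > 0", call. = FALSE)
  }
  if (!(window >= step && step >= 1L)) {
    stop("invalid window config: need window >= step >= 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1 && slope_cut > 0)) {
    stop("invalid neutrality config", call. = FALSE)
  }
  structure(
    list(genetic_code_id = as.integer(genetic_code_id),
         rscu_hi = rscu_hi, rscu_lo = rscu_lo,
         window = as.integer(window), step = as.integer(step),
         alpha = alpha, slope_cut = slope_cut,
         pi_deletion = pi_deletion, seed = seed),
    class = "run_config"
  )
}

#' Combined analysis report for one or more genomes
#'
#' Runs the per-genome chain (dataset composition, codon counts, RSCU with
#' bias classes, start/stop census) and, when several genomes are supplied,
#' the cohort analyses (mean and pooled RSCU, PR2 table, per-gene neutrality
#' fits with force classification). Keyed by accession; serializable to JSON.
#'
#' @param genomes a [mito_genome] or list of them.
#' @param config a [run_config].
#' @return nested list with elements `config`, `genomes` (per accession) and,
#'   for cohorts of two or more, `cohort`.
#' @export
mito_report <- function(genomes, config = run_config()) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L,
            all(vapply(genomes, inherits, TRUE, "mito_genome")))
  code <- genetic_code(config$genetic_code_id)
  per_genome <- lapply(genomes, function(g) {
    cds <- coding_seqs(g, code)
    counts <- count_codons(cds, code, label = g$accession)
    rscu <- classify_rscu(compute_rscu(counts, code),
                          hi = config$rscu_hi, lo = config$rscu_lo)
    census <- start_stop_census(cds)
    list(
      accession = g$accession, organism = g$organism,
      length = nchar(g$sequence), topology = g$topology,
      feature_counts = as.list(table(g$features$category)),
      composition = dataset_composition(g),
      n_sense_codons = counts$n_sense,
      rscu = rscu,
      bias_class_counts = as.list(table(rscu$bias_class)),
      start_census = as.list(census$starts),
      stop_census = as.list(census$stops)
    )
  })
  names(per_genome) <- vapply(genomes, `[[`, "", "accession")
  out <- list(config = unclass(config), genomes = per_genome)
  if (length(genomes) >= 2L) {
    counts_list <- lapply(genomes, function(g)
      count_codons(coding_seqs(g, code), code, label = g$accession))
    pos_tbl <- cohort_positional_table(genomes, code)
    out$cohort <- list(
      n_species = length(genomes),
      rscu_mean = classify_rscu(rscu_pool(counts_list, code, "mean"),
                                config$rscu_hi, config$rscu_lo),
      rscu_pooled = classify_rscu(rscu_pool(counts_list, code, "pooled"),
                                  config$rscu_hi, config$rscu_lo),
      pr2 = cohort_pr2(pos_tbl),
      neutrality = cohort_neutrality(pos_tbl, config$alpha,
                                     config$slope_cut),
      # quadrant convention documented alongside the data
      pr2_quadrants = "I: x>0.5,y>0.5; II: x<0.5,y>0.5; III: x<0.5,y<0.5; IV: x>0.5,y<0.5; boundaries unassigned"
    )
  }
  out
}

#' PR2 bias plot
#'
#' Scatter of `A3/(A3+T3)` against `G3/(G3+C3)` with the neutral center
#' cross at (0.5, 0.5).
#'
#' @param pr2 data.frame from [cohort_pr2()] (or rows from [pr2_point()]
#'   with columns x, y).
#' @param ... passed to [graphics::plot()].
#' @export
plot_pr2 <- function(pr2, ...) {
  graphics::plot(pr2$x, pr2$y, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "G3 / (G3 + C3)", ylab = "A3 / (A3 + T3)",
                 pch = 19, ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey40")
}

#' Neutrality plot
#'
#' GC12 against GC3 with the fitted regression line and the 1:1 diagonal.
#'
#' @param gc3,gc12 numeric vectors.
#' @param fit optional [neutrality_fit]; computed if missing.
#' @param ... passed to [graphics::plot()].
#' @export
plot_neutrality <- function(gc3, gc12, fit = NULL, ...) {
  if (is.null(fit)) fit <- neutrality_fit(gc3, gc12)
  graphics::plot(gc3, gc12, xlab = "GC3", ylab = "GC12", pch = 19, ...)
  graphics::abline(fit$intercept, fit$slope, col = "firebrick")
  graphics::abline(0, 1, lty = 3, col = "grey50")
}

#' Sliding-window diversity profile
#'
#' @param windows data.frame from [sliding_window_pi()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_pi_windows <- function(windows, ...) {
  graphics::plot(windows$start, windows$pi, type = "l",
                 xlab = "window start (alignment column)",
                 ylab = expression(pi), ...)
}
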