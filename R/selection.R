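# Mutation-pressure vs natural-selection analyses of codon usage bias:
# the parity-rule-2 (PR2) bias plot of third-codon-position composition, and
# the neutrality plot (OLS regression of GC12 on GC3 with a Pearson test).
#
# PR2: under strand-symmetric mutation alone, A = T and G = C at third
# positions, so every gene sits at (0.5, 0.5); displacement marks the joint
# action of mutation and selection. Neutrality plot: a slope near 1 with a
# significant GC12~GC3 correlation indicates dominant mutation pressure, a
# slope near 0 with no correlation indicates dominant selection.

#' PR2 bias-plot coordinates of a gene
#'
#' `x = G3/(G3+C3)`, `y = A3/(A3+T3)` over third positions of all sense
#' codons. The Cartesian quadrant is assigned as I: x>0.5, y>0.5; II: x<0.5,
#' y>0.5; III: x<0.5, y<0.5; IV: x>0.5, y<0.5; boundary values (exactly 0.5)
#' belong to no quadrant (`NA`).
#'
#' @param pc a [positional_composition].
#' @param label point label (gene or species:gene).
#' @return one-row data.frame: label, x, y, quadrant.
#' @export
pr2_point <- function(pc, label = "") {
  stopifnot(inherits(pc, "positional_composition"))
  a3 <- pc$counts["p3", "A"]; t3 <- pc$counts["p3", "T"]
  g3 <- pc$counts["p3", "G"]; c3 <- pc$counts["p3", "C"]
  if (g3 + c3 == 0) {
    stop("PR2 x-axis undefined for ", label, ": G3 + C3 = 0", call. = FALSE)
  }
  if (a3 + t3 == 0) {
    stop("PR2 y-axis undefined for ", label, ": A3 + T3 = 0", call. = FALSE)
  }
  x <- g3 / (g3 + c3)
  y <- a3 / (a3 + t3)
  quadrant <- if (x == 0.5 || y == 0.5) {
    NA_character_
  } else if (x > 0.5 && y > 0.5) "I" else if (x < 0.5 && y > 0.5) "II" else
    if (x < 0.5 && y < 0.5) "III" else "IV"
  data.frame(label = label, x = x, y = y, quadrant = quadrant,
             stringsAsFactors = FALSE)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 on GC3 plus the Pearson correlation with
#' its exact two-sided t-test on n - 2 degrees of freedom.
#'
#' @param gc3,gc12 numeric vectors of per-gene (or per-species) GC3 and GC12
#'   fractions; `gc12` may be omitted if `gc3` is a two-column matrix or
#'   data.frame `(gc3, gc12)`.
#' @return object of class `neutrality_fit`: list with `n`, `slope`,
#'   `intercept`, `pearson_r`, `p_value`.
#' @export
neutrality_fit <- function(gc3, gc12 = NULL) {
  if (is.null(gc12)) {
    stopifnot(ncol(gc3) == 2L)
    gc12 <- gc3[, 2]; gc3 <- gc3[, 1]
  }
  gc3 <- as.numeric(gc3); gc12 <- as.numeric(gc12)
  stopifnot(length(gc3) == length(gc12))
  n <- length(gc3)
  if (n < 3L) {
    stop("insufficient data for a neutrality fit: n = ", n, " < 3",
         call. = FALSE)
  }
  if (var(gc3) == 0) {
    stop("degenerate fit: GC3 values are all equal", call. = FALSE)
  }
  fit <- lm(gc12 ~ gc3)
  if (var(gc12) == 0) {
    r <- 0; p <- 1  # flat response: no association, by convention
  } else {
    ct <- cor.test(gc3, gc12, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(
    list(n = n, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         pearson_r = r, p_value = p),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "<neutrality_fit> n=%d  GC12 = %.4f + %.4f GC3   r=%.4f, p=%.4g\n",
    x$n, x$intercept, x$slope, x$pearson_r, x$p_value))
  invisible(x)
}

#' Classify the dominant force shaping codon usage
#'
#' Mechanical rule over the neutrality fit: a non-significant correlation
#' (`p >= alpha`) means selection dominates; a significant correlation with
#' slope at or above `slope_cut` means mutation pressure dominates; a
#' significant correlation with a shallower slope marks co-dominance of the
#' two forces.
#'
#' @param fit a [neutrality_fit].
#' @param alpha significance level (default 0.05).
#' @param slope_cut slope threshold separating mutation dominance from
#'   co-dominance (default 0.5).
#' @return one of `"selection_dominant"`, `"mutation_dominant"`,
#'   `"co_dominant"`.
#' @export
classify_forces <- function(fit, alpha = 0.05, slope_cut = 0.5) {
  stopifnot(inherits(fit, "neutrality_fit"))
  if (fit$p_value >= alpha) {
    "selection_dominant"
  } else if (fit$slope >= slope_cut) {
    "mutation_dominant"
  } else {
    "co_dominant"
  }
}

#' Per-species, per-gene positional composition table for a cohort
#'
#' The working table behind both the PR2 and neutrality analyses: one row per
#' (species, gene) with third-position base counts, GC3 and GC12.
#'
#' @param genomes list of [mito_genome] objects.
#' @param code a [genetic_code].
#' @return data.frame with columns species, gene, n_codons, a3, t3, g3, c3,
#'   gc3, gc12.
#' @export
cohort_positional_table <- function(genomes, code = genetic_code(5)) {
  rows <- lapply(genomes, function(g) {
    cds <- coding_seqs(g, code)
    do.call(rbind, lapply(names(cds), function(gene) {
      pc <- positional_composition(cds[[gene]])
      data.frame(species = g$accession, gene = gene,
                 n_codons = pc$n_codons,
                 a3 = pc$counts["p3", "A"], t3 = pc$counts["p3", "T"],
                 g3 = pc$counts["p3", "G"], c3 = pc$counts["p3", "C"],
                 gc3 = pc$gc3, gc12 = pc$gc12,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort PR2 table
#'
#' @param pos_tbl output of [cohort_positional_table()].
#' @return data.frame with species, gene, x, y, quadrant.
#' @export
cohort_pr2 <- function(pos_tbl) {
  out <- do.call(rbind, lapply(seq_len(nrow(pos_tbl)), function(i) {
    r <- pos_tbl[i, ]
    x <- r$g3 / (r$g3 + r$c3)
    y <- r$a3 / (r$a3 + r$t3)
    quadrant <- if (x == 0.5 || y == 0.5) NA_character_ else
      if (x > 0.5 && y > 0.5) "I" else if (x < 0.5 && y > 0.5) "II" else
        if (x < 0.5 && y < 0.5) "III" else "IV"
    data.frame(species = r$species, gene = r$gene, x = x, y = y,
               quadrant = quadrant, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene neutrality fits over a cohort
#'
#' Fits GC12 on GC3 across species for each gene and classifies the dominant
#' force.
#'
#' @param pos_tbl output of [cohort_positional_table()].
#' @param alpha,slope_cut see [classify_forces()].
#' @return data.frame with gene, n, slope, intercept, pearson_r, p_value,
#'   classification.
#' @export
cohort_neutrality <- function(pos_tbl, alpha = 0.05, slope_cut = 0.5) {
  out <- do.call(rbind, lapply(split(pos_tbl, pos_tbl$gene), function(d) {
    fit <- neutrality_fit(d$gc3, d$gc12)
    data.frame(gene = d$gene[1], n = fit$n, slope = fit$slope,
               intercept = fit$intercept, pearson_r = fit$pearson_r,
               p_value = fit$p_value,
               classification = classify_forces(fit, alpha, slope_cut),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
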