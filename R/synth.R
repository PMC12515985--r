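# Synthetic mitogenomes, coding-sequence sets and star-phylogeny alignments
# with recorded ground truth, so every pipeline stage can be tested without
# external data. Defaults emulate a stylommatophoran land-snail mitogenome:
# a circular ~15 kb molecule carrying 13 PCGs (~10.9 kb), 22 tRNAs (63 nt
# each) and 2 rRNAs split across both strands, AT-rich (70%) with a negative
# AT skew and positive GC skew on the deposited strand.

.dna_bases <- c("A", "C", "G", "T")

# deposited-strand base probabilities implied by content/skew targets
base_probs <- function(at, at_skew, gc_skew) {
  c(A = at * (1 + at_skew) / 2,
    C = (1 - at) * (1 - gc_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2,
    T = at * (1 - at_skew) / 2)[.dna_bases]
}

#' Codon frequency vector matching a base-composition target
#'
#' Builds a 62-entry sense-codon probability vector as an independent-site
#' product measure over a base distribution, with the base AT level
#' calibrated (by root finding) so that the expected per-base AT content of
#' the sampled codons equals `at_target` exactly — the renormalization after
#' removing the AT-rich stop codons would otherwise shift it.
#'
#' @param at_target target AT fraction of coding sequence.
#' @param at_skew,gc_skew skew targets of the coding strand.
#' @param code a [genetic_code].
#' @return named numeric vector over `code$sense`, summing to 1.
#' @export
codon_freqs_from_composition <- function(at_target = 0.70, at_skew = -0.10,
                                         gc_skew = 0.10,
                                         code = genetic_code(5)) {
  stopifnot(at_target > 0.02, at_target < 0.98)
  base_mat <- do.call(rbind, strsplit(code$sense, ""))
  freqs_at <- function(at) {
    p <- base_probs(at, at_skew, gc_skew)
    f <- p[base_mat[, 1]] * p[base_mat[, 2]] * p[base_mat[, 3]]
    f / sum(f)
  }
  at_of <- function(at) {
    f <- freqs_at(at)
    at_counts <- rowSums(base_mat == "A" | base_mat == "T")
    sum(f * at_counts) / 3
  }
  root <- stats::uniroot(function(at) at_of(at) - at_target,
                         lower = 0.02, upper = 0.98, tol = 1e-10)
  f <- freqs_at(root$root)
  setNames(as.numeric(f), code$sense)
}

#' Default 37-gene layout
#'
#' Gene order, categories, strands and sizes for the synthetic mitogenome:
#' 9 PCGs + rrnL + 13 tRNAs on the H strand, 4 PCGs + rrnS + 9 tRNAs on the
#' L strand. PCG sizes are codon counts (start included, stop excluded);
#' RNA sizes are nucleotides.
#'
#' @return data.frame with columns gene, category, strand, size.
#' @export
default_gene_layout <- function() {
  pcg_codons <- c(COX1 = 512, COX2 = 218, COX3 = 256, CYTB = 370,
                  NAD1 = 295, NAD2 = 310, NAD3 = 112, NAD4 = 430,
                  NAD4L = 97, NAD5 = 542, NAD6 = 155, ATP6 = 215, ATP8 = 52)
  l_pcgs <- c("COX3", "NAD3", "NAD6", "ATP8")
  l_trnas <- c("trnC", "trnE", "trnG", "trnH", "trnQ", "trnS2", "trnV",
               "trnW", "trnY")
  order_ <- c("COX1", "trnV", "rrnL", "trnL1", "trnA", "ATP8", "trnN",
              "ATP6", "trnR", "trnE", "rrnS", "trnM", "NAD3", "trnS2",
              "trnT", "COX3", "trnS1", "NAD4", "trnH", "NAD5", "trnW",
              "trnQ", "trnL2", "trnG", "NAD1", "trnP", "NAD6", "CYTB",
              "trnD", "trnC", "trnF", "COX2", "trnY", "trnK", "NAD2",
              "trnI", "NAD4L")
  category <- gene_category(order_)
  size <- ifelse(category == "PCG", pcg_codons[order_],
                 ifelse(order_ == "rrnS", 760L,
                        ifelse(order_ == "rrnL", 920L, 62L)))
  strand <- ifelse(order_ %in% c(l_pcgs, l_trnas, "rrnS"), "L", "H")
  data.frame(gene = order_, category = category, strand = strand,
             size = as.integer(size), stringsAsFactors = FALSE)
}

#' Specification of a synthetic mitogenome
#'
#' @param length_target total genome length in nt (default 15,000).
#' @param at_target whole-genome AT fraction target (default 0.70).
#' @param at_skew_target,gc_skew_target deposited-strand skew targets
#'   (defaults -0.10 and +0.10).
#' @param codon_freqs 62-entry sense-codon probability vector; default built
#'   by [codon_freqs_from_composition()] from the composition targets.
#' @param start_mix,stop_mix named probability vectors for PCG start codons
#'   and stop tails (`T` and `TA` are the incomplete stops).
#' @param layout gene layout data.frame (see [default_gene_layout()]).
#' @param code a [genetic_code].
#' @param seed RNG seed.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(length_target = 15000L, at_target = 0.70,
                        at_skew_target = -0.10, gc_skew_target = 0.10,
                        codon_freqs = NULL,
                        start_mix = c(ATG = 0.6, ATA = 0.2, ATT = 0.1,
                                      TTG = 0.1),
                        stop_mix = c(TAA = 0.6, TAG = 0.2, T = 0.1,
                                     TA = 0.1),
                        layout = default_gene_layout(),
                        code = genetic_code(5), seed = 1L) {
  stopifnot(at_target > 0, at_target < 1,
            abs(at_skew_target) <= 1, abs(gc_skew_target) <= 1,
            abs(sum(start_mix) - 1) < 1e-8, abs(sum(stop_mix) - 1) < 1e-8)
  tab <- table(layout$category)
  if (!(identical(unname(tab[["PCG"]]), 13L) &&
        identical(unname(tab[["tRNA"]]), 22L) &&
        identical(unname(tab[["rRNA"]]), 2L))) {
    stop("layout must contain 13 PCGs, 22 tRNAs and 2 rRNAs", call. = FALSE)
  }
  if (is.null(codon_freqs)) {
    codon_freqs <- codon_freqs_from_composition(
      at_target, at_skew_target, gc_skew_target, code)
  }
  stopifnot(length(codon_freqs) == length(code$sense),
            abs(sum(codon_freqs) - 1) < 1e-8)
  structure(
    list(length_target = as.integer(length_target), at_target = at_target,
         at_skew_target = at_skew_target, gc_skew_target = gc_skew_target,
         codon_freqs = codon_freqs, start_mix = start_mix,
         stop_mix = stop_mix, layout = layout, code = code,
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Simulate an annotated circular mitogenome with ground truth
#'
#' PCGs are built by sampling sense codons from `codon_freqs`, prepending a
#' start codon from `start_mix` and appending a stop (complete TAA/TAG or an
#' incomplete T/TA tail) from `stop_mix`; L-strand genes are stored
#' reverse-complemented in the deposited sequence. RNA genes are drawn
#' i.i.d. at the composition targets. Intergenic filler is constructed with
#' the exact residual base counts needed to bring the whole deposited strand
#' to the content/skew targets; when the genic sequence alone already
#' overshoots a target by more than 2% of the genome an infeasibility error
#' is raised.
#'
#' @param spec a [genome_spec].
#' @return list with `genome` (a [mito_genome]) and `truth`, a list
#'   recording per-gene coding sequences and codon counts, per-dataset
#'   concatenations, and the start/stop census — everything the pipeline is
#'   expected to recover from the emitted record.
#' @export
simulate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  code <- spec$code
  with_seed(spec$seed, {
    layout <- spec$layout
    rna_probs <- base_probs(spec$at_target, spec$at_skew_target,
                            spec$gc_skew_target)
    gene_nt <- character(nrow(layout))      # coding-strand sequence
    start_codons <- stop_labels <- setNames(
      rep(NA_character_, nrow(layout)), layout$gene)
    for (i in seq_len(nrow(layout))) {
      if (layout$category[i] == "PCG") {
        start <- sample(names(spec$start_mix), 1L, prob = spec$start_mix)
        body <- sample(code$sense, layout$size[i] - 1L, replace = TRUE,
                       prob = spec$codon_freqs)
        stop_ <- sample(names(spec$stop_mix), 1L, prob = spec$stop_mix)
        gene_nt[i] <- paste0(start, paste(body, collapse = ""), stop_)
        start_codons[i] <- start
        stop_labels[i] <- switch(stop_, T = "T-", TA = "TA-", stop_)
      } else {
        gene_nt[i] <- paste(
          sample(.dna_bases, layout$size[i], replace = TRUE,
                 prob = rna_probs),
          collapse = "")
      }
    }
    deposited <- ifelse(layout$strand == "L",
                        vapply(gene_nt, revcomp, ""), gene_nt)

    genic_len <- sum(nchar(deposited))
    n_fill <- spec$length_target - genic_len
    if (n_fill < 0L) {
      stop("infeasible spec: genic length ", genic_len,
           " exceeds length target ", spec$length_target, call. = FALSE)
    }
    filler <- make_filler(deposited, n_fill, spec)

    # spread the filler over the 37 intergenic gaps; the gap after rrnS gets
    # most of it, mimicking a large non-coding/control region
    wt <- rep(1, nrow(layout))
    wt[which(layout$gene == "rrnS")] <- 25
    alloc <- as.integer(stats::rmultinom(1, n_fill, wt))
    pieces <- character(2L * nrow(layout))
    intervals <- vector("list", nrow(layout))
    pos <- 1L
    fill_pos <- 1L
    for (i in seq_len(nrow(layout))) {
      len <- nchar(deposited[i])
      intervals[[i]] <- matrix(c(pos, pos + len - 1L), ncol = 2L,
                               dimnames = list(NULL, c("start", "end")))
      pieces[2L * i - 1L] <- deposited[i]
      if (alloc[i] > 0L) {
        pieces[2L * i] <- substr(filler, fill_pos, fill_pos + alloc[i] - 1L)
        fill_pos <- fill_pos + alloc[i]
      }
      pos <- pos + len + alloc[i]
    }
    sequence <- paste(pieces, collapse = "")

    features <- data.frame(
      gene = layout$gene, category = layout$category,
      strand = layout$strand, codon_table = code$id,
      label_raw = layout$gene, stringsAsFactors = FALSE)
    features$intervals <- I(intervals)
    genome <- mito_genome(sequence, features, accession = "SYNTH",
                          organism = "synthetic mitogenome",
                          topology = "circular")

    is_pcg <- layout$category == "PCG"
    per_gene_counts <- lapply(which(is_pcg), function(i) {
      trimmed <- classify_coding_seq(gene_nt[i], layout$gene[i],
                                     code)$trimmed_nt
      count_codons(trimmed, code, label = layout$gene[i])
    })
    names(per_gene_counts) <- layout$gene[is_pcg]
    truth <- list(
      spec = spec,
      gene_nt = setNames(gene_nt, layout$gene),
      dataset_seqs = list(
        whole = sequence,
        PCGs = paste(gene_nt[is_pcg], collapse = ""),
        tRNAs = paste(gene_nt[layout$category == "tRNA"], collapse = ""),
        rRNAs = paste(gene_nt[layout$category == "rRNA"], collapse = "")),
      per_gene_counts = per_gene_counts,
      start_codons = start_codons[is_pcg],
      stop_labels = stop_labels[is_pcg],
      n_fill = n_fill)
    list(genome = genome, truth = truth)
  })
}

# filler with the exact residual base counts needed to hit the targets
make_filler <- function(deposited_genes, n_fill, spec) {
  target <- spec$length_target *
    base_probs(spec$at_target, spec$at_skew_target, spec$gc_skew_target)
  b <- chars(paste(deposited_genes, collapse = ""))
  genic <- vapply(.dna_bases, function(x) sum(b == x), numeric(1))
  resid <- target - genic
  deficit <- sum(-pmin(resid, 0))
  if (deficit > 0.02 * spec$length_target) {
    stop("infeasible composition targets: genic sequence overshoots the ",
         "base targets by ", round(deficit), " nt (> 2% of the genome)",
         call. = FALSE)
  }
  resid <- pmax(resid, 0)
  if (n_fill == 0L) return("")
  if (sum(resid) == 0) {
    resid <- base_probs(spec$at_target, spec$at_skew_target,
                        spec$gc_skew_target)
  }
  alloc <- floor(resid * n_fill / sum(resid))
  short <- n_fill - sum(alloc)
  if (short > 0L) {
    frac <- resid * n_fill / sum(resid) - alloc
    alloc[order(frac, decreasing = TRUE)[seq_len(short)]] <-
      alloc[order(frac, decreasing = TRUE)[seq_len(short)]] + 1L
  }
  paste(sample(rep(.dna_bases, times = alloc)), collapse = "")
}

#' Simulate coding sequences from a codon-frequency vector
#'
#' Each gene is a run of sense codons drawn i.i.d. from `codon_freqs`, closed
#' by a TAA stop. The recorded truth includes the analytic expected RSCU:
#' `E[RSCU(c)] = freq(c) * family_size / sum(freq over the family)`.
#'
#' @param codon_freqs named probability vector over the sense codons;
#'   default from [codon_freqs_from_composition()].
#' @param n_genes,codons_per_gene set dimensions (defaults 13 and 100).
#' @param code a [genetic_code].
#' @param seed RNG seed.
#' @return list with `cds` (list of `coding_seq`) and `truth` (list with
#'   `codon_freqs` and `expected_rscu`, a data.frame codon/expected_rscu).
#' @export
simulate_codingseqs <- function(codon_freqs = NULL, n_genes = 13L,
                                codons_per_gene = 100L,
                                code = genetic_code(5), seed = 1L) {
  if (is.null(codon_freqs)) {
    codon_freqs <- codon_freqs_from_composition(code = code)
  }
  stopifnot(length(codon_freqs) == length(code$sense),
            abs(sum(codon_freqs) - 1) < 1e-8)
  codon_freqs <- setNames(as.numeric(codon_freqs), code$sense)
  cds <- with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      body <- paste(sample(code$sense, codons_per_gene, replace = TRUE,
                           prob = codon_freqs), collapse = "")
      new_coding_seq(gene = sprintf("G%02d", g),
                     nt = paste0(body, "TAA"),
                     start_codon = substr(body, 1, 3),
                     stop_kind = "complete", stop_codon = "TAA",
                     trimmed_nt = body)
    })
  })
  aa <- code$map[code$sense]
  fam_sum <- tapply(codon_freqs, aa, sum)[aa]
  expected <- data.frame(
    codon = code$sense,
    expected_rscu = as.numeric(codon_freqs * code$family_size[code$sense] /
                                 fam_sum),
    stringsAsFactors = FALSE)
  rownames(expected) <- expected$codon
  list(cds = cds,
       truth = list(codon_freqs = codon_freqs, expected_rscu = expected))
}

#' Simulate a star-phylogeny alignment with analytic expected diversity
#'
#' Every taxon descends independently from one uniform-random ancestral row;
#' each site mutates with probability `p_sub` to one of the three other
#' bases, uniformly (a single-hit Jukes-Cantor-like step per lineage). Two
#' lineages then differ at a site with probability
#' `2 p (1 - p) + (2/3) p^2`, which is the analytic expected pi stored in
#' the truth record. Alignments are gap-free by construction.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param n_columns alignment length.
#' @param p_sub per-lineage substitution probability in `[0, 0.75]`; a
#'   scalar, or one value per partition for rate heterogeneity.
#' @param partitions optional data.frame `gene, length` defining contiguous
#'   partitions (lengths must sum to `n_columns`).
#' @param seed RNG seed.
#' @return list with `aln` (a [multi_alignment]) and `truth` (per-column
#'   `p_sub`, `expected_pi` overall, and `expected_pi_partition` when
#'   partitioned).
#' @export
simulate_alignment <- function(n_taxa = 20L, n_columns = 10000L,
                               p_sub = 0.1, partitions = NULL, seed = 1L) {
  stopifnot(n_taxa >= 2L, n_columns >= 1L)
  if (any(p_sub < 0 | p_sub > 0.75)) {
    stop("p_sub must lie in [0, 0.75]", call. = FALSE)
  }
  part_df <- NULL
  if (!is.null(partitions)) {
    stopifnot(is.data.frame(partitions),
              all(c("gene", "length") %in% names(partitions)),
              sum(partitions$length) == n_columns)
    ends <- cumsum(partitions$length)
    part_df <- data.frame(gene = partitions$gene,
                          start = c(1L, head(ends, -1L) + 1L),
                          end = ends, stringsAsFactors = FALSE)
    if (length(p_sub) == 1L) p_sub <- rep(p_sub, nrow(partitions))
    stopifnot(length(p_sub) == nrow(partitions))
    p_col <- rep(p_sub, times = partitions$length)
  } else {
    stopifnot(length(p_sub) == 1L)
    p_col <- rep(p_sub, n_columns)
  }
  rows <- with_seed(seed, {
    anc <- sample(.dna_bases, n_columns, replace = TRUE)
    anc_idx <- match(anc, .dna_bases)
    vapply(seq_len(n_taxa), function(k) {
      mut <- runif(n_columns) < p_col
      idx <- anc_idx
      if (any(mut)) {
        shift <- sample.int(3L, sum(mut), replace = TRUE)
        idx[mut] <- (anc_idx[mut] - 1L + shift) %% 4L + 1L
      }
      paste(.dna_bases[idx], collapse = "")
    }, character(1))
  })
  names(rows) <- sprintf("t%02d", seq_len(n_taxa))
  e_pi <- function(p) 2 * p * (1 - p) + (2 / 3) * p^2
  truth <- list(p_col = p_col, expected_pi = mean(e_pi(p_col)))
  if (!is.null(part_df)) {
    truth$expected_pi_partition <- data.frame(
      gene = part_df$gene, p_sub = p_sub, expected_pi = e_pi(p_sub),
      stringsAsFactors = FALSE)
  }
  list(aln = multi_alignment(rows, partitions = part_df), truth = truth)
}
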