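# The synthetic generator: its outputs must be reproducible and its recorded
# truth must be recoverable by running the main pipeline on the emitted data
# — that agreement is the module's core cross-check.

test_that("synthetic genomes carry the canonical 37-gene inventory", {
  sim <- simulate_mitogenome(genome_spec(seed = 81))
  tab <- table(sim$genome$features$category)
  expect_equal(unname(tab[["PCG"]]), 13L)
  expect_equal(unname(tab[["tRNA"]]), 22L)
  expect_equal(unname(tab[["rRNA"]]), 2L)
  expect_equal(sim$genome$topology, "circular")
  voc <- mito_gene_vocabulary()
  expect_setequal(sim$genome$features$gene,
                  c(voc$PCG, voc$tRNA, voc$rRNA))
  # strand economy: 9 PCGs + rrnL + 13 tRNAs on H
  f <- sim$genome$features
  expect_equal(sum(f$category == "PCG" & f$strand == "H"), 9L)
  expect_equal(sum(f$category == "tRNA" & f$strand == "H"), 13L)
  expect_equal(f$strand[f$gene == "rrnL"], "H")
  expect_equal(f$strand[f$gene == "rrnS"], "L")
})

test_that("identical spec and seed give identical genomes; seeds differ", {
  a <- simulate_mitogenome(genome_spec(seed = 5))
  b <- simulate_mitogenome(genome_spec(seed = 5))
  c <- simulate_mitogenome(genome_spec(seed = 6))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("realized whole-genome composition lands on the targets", {
  spec <- genome_spec(length_target = 14000L, at_target = 0.70, seed = 82)
  sim <- simulate_mitogenome(spec)
  bc <- base_composition(sim$genome$sequence)
  expect_equal(nchar(sim$genome$sequence), 14000L)
  expect_lt(abs(bc$at_content - 0.70), 0.02)
  # with the default length there is enough intergenic filler for the
  # residual-count construction to land the skews as well
  bc2 <- base_composition(simulate_mitogenome(
    genome_spec(seed = 82))$genome$sequence)
  expect_lt(abs(bc2$at_content - 0.70), 0.02)
  expect_lt(abs(bc2$at_skew - (-0.10)), 0.05)
  expect_lt(abs(bc2$gc_skew - 0.10), 0.05)
})

test_that("infeasible composition targets raise a feasibility error", {
  spec <- genome_spec(length_target = 14000L, seed = 83)
  spec$at_target <- 0.995  # genic sequence cannot be compensated
  expect_error(simulate_mitogenome(spec), "infeasible")
  expect_error(simulate_mitogenome(genome_spec(length_target = 12000L,
                                               seed = 83)),
               "exceeds length target")
})

test_that("every emitted PCG re-extracts cleanly with no internal stop", {
  sim <- simulate_mitogenome(genome_spec(seed = 84))
  path <- tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  g <- read_genbank(path)
  cds <- coding_seqs(g)   # classify_coding_seq errors on internal stops
  expect_length(cds, 13L)
  code <- genetic_code(5)
  for (cs in cds) {
    aa <- code$map[mitocub:::codons_of(cs$trimmed_nt)]
    expect_false(any(aa == "*"))
  }
})

test_that("pipeline recovers the generator's bookkept truth from the genome", {
  sim <- simulate_mitogenome(genome_spec(seed = 85))
  g <- sim$genome
  # dataset concatenations agree
  for (cat_ in c("PCG", "tRNA", "rRNA")) {
    expect_equal(concat_gene_set(g, cat_)$sequence,
                 sim$truth$dataset_seqs[[paste0(cat_, "s")]])
  }
  # per-gene codon counts agree
  cds <- coding_seqs(g)
  for (gene in names(sim$truth$per_gene_counts)) {
    expect_equal(count_codons(cds[[gene]], label = gene)$counts,
                 sim$truth$per_gene_counts[[gene]]$counts)
  }
  # census agrees with the drawn start/stop mixture
  cen <- start_stop_census(cds)
  expect_equal(sum(cen$starts), 13L)
  expect_equal(c(cen$starts), c(table(sim$truth$start_codons)))
  expect_equal(c(cen$stops), c(table(sim$truth$stop_labels)))
})

test_that("simulated coding sets recover expected RSCU within sampling error", {
  code <- genetic_code(5)
  # a family weighted 3:1 has expected RSCU 1.5 / 0.5
  freqs <- setNames(rep(1, 62), code$sense)
  freqs[["AAA"]] <- 3; freqs[["AAG"]] <- 1
  freqs <- freqs / sum(freqs)
  sim <- simulate_codingseqs(freqs, n_genes = 10, codons_per_gene = 1000,
                             seed = 86)
  expect_equal(sim$truth$expected_rscu["AAA", "expected_rscu"], 1.5)
  expect_equal(sim$truth$expected_rscu["AAG", "expected_rscu"], 0.5)
  obs <- compute_rscu(count_codons(sim$cds, code), code)
  expect_lt(abs(obs["AAA", "rscu"] - 1.5), 0.1)
  # uniform frequencies within every family: expected RSCU 1 everywhere
  uni <- simulate_codingseqs(setNames(rep(1 / 62, 62), code$sense),
                             n_genes = 10, codons_per_gene = 1000,
                             seed = 87)
  expect_true(all(uni$truth$expected_rscu$expected_rscu == 1))
  obs_u <- compute_rscu(count_codons(uni$cds, code), code)
  expect_lt(max(abs(obs_u$rscu - 1)), 0.25)
  # determinism
  again <- simulate_codingseqs(freqs, n_genes = 10, codons_per_gene = 1000,
                               seed = 86)
  expect_identical(vapply(again$cds, `[[`, "", "nt"),
                   vapply(sim$cds, `[[`, "", "nt"))
})

test_that("star-phylogeny alignments match their analytic diversity", {
  s0 <- simulate_alignment(n_taxa = 6, n_columns = 500, p_sub = 0,
                           seed = 88)
  expect_equal(length(unique(s0$aln$seqs)), 1L)
  expect_equal(nucleotide_diversity(s0$aln)$pi, 0)
  expect_equal(s0$truth$expected_pi, 0)

  s1 <- simulate_alignment(n_taxa = 20, n_columns = 10000, p_sub = 0.1,
                           seed = 89)
  expect_equal(s1$truth$expected_pi, 2 * 0.1 * 0.9 + (2 / 3) * 0.01)
  obs <- nucleotide_diversity(s1$aln)$pi
  # Monte-Carlo SE from the per-column mismatch fractions
  mat <- s1$aln$mat
  col_pi <- vapply(seq_len(ncol(mat)), function(k) {
    tab <- table(mat[, k])
    n <- sum(tab)
    1 - sum(choose(tab, 2)) / choose(n, 2)
  }, numeric(1))
  se <- sd(col_pi) / sqrt(length(col_pi))
  expect_lt(abs(obs - s1$truth$expected_pi), 3 * se)
  expect_error(simulate_alignment(p_sub = 0.9), "0.75")
})

test_that("per-partition substitution rates produce ordered diversity", {
  parts <- data.frame(gene = c("g1", "g2", "g3"), length = c(600, 600, 600))
  sim <- simulate_alignment(n_taxa = 15, n_columns = 1800,
                            p_sub = c(0.02, 0.10, 0.30),
                            partitions = parts, seed = 90)
  expect_equal(sim$truth$expected_pi_partition$expected_pi,
               2 * c(0.02, 0.1, 0.3) * (1 - c(0.02, 0.1, 0.3)) +
                 (2 / 3) * c(0.02, 0.1, 0.3)^2)
  pp <- per_partition_pi(sim$aln)
  expect_true(all(diff(pp$pi) > 0))
})

test_that("codon frequency construction hits its AT calibration target", {
  code <- genetic_code(5)
  for (at in c(0.60, 0.70, 0.76)) {
    f <- codon_freqs_from_composition(at_target = at, code = code)
    expect_equal(sum(f), 1)
    base_mat <- do.call(rbind, strsplit(code$sense, ""))
    at_exp <- sum(f * rowSums(base_mat == "A" | base_mat == "T")) / 3
    expect_equal(at_exp, at, tolerance = 1e-8)
  }
})
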