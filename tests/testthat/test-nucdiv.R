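# Nucleotide diversity: global, sliding-window and per-partition.

test_that("pi matches hand values on two-row alignments", {
  aln <- multi_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  expect_equal(nucleotide_diversity(aln)$pi, 0.1)
  aln2 <- multi_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(nucleotide_diversity(aln2)$pi, 0)
})

test_that("pi equals brute-force pairwise enumeration on random small alignments", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      n_rows <- sample(3:6, 1)
      rows <- vapply(seq_len(n_rows), function(i) rand_dna(30), "")
      # sprinkle gaps and Ns
      rows[1] <- paste0("--", substr(rows[1], 3, 30))
      rows[2] <- paste0(substr(rows[2], 1, 28), "NN")
      aln <- multi_alignment(setNames(rows, paste0("t", seq_len(n_rows))))
      expect_equal(nucleotide_diversity(aln)$pi, pi_oracle(rows))
    }
  })
})

test_that("pairwise deletion counts per-pair comparable sites; complete deletion drops columns", {
  rows <- c(a = "AAAA", b = "AAC-", c = "TA-N")
  aln <- multi_alignment(rows)
  res <- nucleotide_diversity(aln)
  # pairs: a-b 1/3 over cols 1-3, a-c 1/2 over cols 1-2, b-c 1/2 over 1-2
  expect_equal(res$pi, mean(c(1 / 3, 1 / 2, 1 / 2)))
  expect_equal(res$n_sites_used, 3L)  # column 4 has no comparable pair
  resc <- nucleotide_diversity(aln, deletion = "complete")
  # only columns 1-2 survive; pairs: a-b 0/2, a-c 1/2, b-c 1/2
  expect_equal(resc$pi, mean(c(0, 1 / 2, 1 / 2)))
  expect_error(
    nucleotide_diversity(multi_alignment(c(a = "A-", b = "-A"))),
    "no sequence pair")
})

test_that("pi is invariant to row and column reordering", {
  withr::with_seed(72, {
    rows <- vapply(1:5, function(i) rand_dna(40), "")
  })
  aln <- multi_alignment(setNames(rows, paste0("t", 1:5)))
  base_pi <- nucleotide_diversity(aln)$pi
  perm_rows <- multi_alignment(setNames(rows[c(4, 1, 5, 3, 2)],
                                        paste0("t", 1:5)))
  expect_equal(nucleotide_diversity(perm_rows)$pi, base_pi)
  colperm <- sample(40)
  shuffled <- vapply(rows, function(s)
    paste(strsplit(s, "")[[1]][colperm], collapse = ""), "")
  expect_equal(
    nucleotide_diversity(multi_alignment(setNames(shuffled,
                                                  paste0("t", 1:5))))$pi,
    base_pi)
})

test_that("duplicating an existing row cannot increase pi", {
  withr::with_seed(73, {
    for (rep in 1:5) {
      rows <- vapply(1:4, function(i) rand_dna(25), "")
      aln <- multi_alignment(setNames(rows, paste0("t", 1:4)))
      dup <- multi_alignment(setNames(c(rows, rows[1]), paste0("t", 1:5)))
      expect_lte(nucleotide_diversity(dup)$pi,
                 nucleotide_diversity(aln)$pi + 1e-12)
    }
  })
})

test_that("pi agrees with ape's raw pairwise-deletion distances", {
  skip_if_not_installed("ape")
  withr::with_seed(74, {
    rows <- vapply(1:6, function(i) rand_dna(120), "")
  })
  aln <- multi_alignment(setNames(rows, paste0("t", 1:6)))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(rows), "")))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  expect_equal(nucleotide_diversity(aln)$pi, mean(d))
})

test_that("sliding windows anchor at column 1, advance by step, drop partial tails", {
  withr::with_seed(75, {
    rows <- vapply(1:4, function(i) rand_dna(400), "")
  })
  aln <- multi_alignment(setNames(rows, paste0("t", 1:4)))
  w <- sliding_window_pi(aln, window = 200, step = 20)
  expect_equal(nrow(w), 11L)             # (400 - 200)/20 + 1
  expect_equal(w$start[1], 1L)
  expect_equal(w$start[11], 201L)
  expect_equal(w$end[11], 400L)
  # window == alignment length reduces to global pi
  w1 <- sliding_window_pi(aln, window = 400, step = 20)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$pi, nucleotide_diversity(aln)$pi)
  # oversized window truncates with a warning
  expect_warning(wt <- sliding_window_pi(aln, window = 500, step = 20),
                 "truncated")
  expect_equal(wt$end, 400L)
  expect_error(sliding_window_pi(aln, window = 10, step = 20), "window >= step")
})

test_that("all-identical alignments give zero pi in every window", {
  rows <- setNames(rep(strrep("ACGT", 75), 3), paste0("t", 1:3))
  w <- sliding_window_pi(multi_alignment(rows), window = 100, step = 20)
  expect_true(all(w$pi == 0))
})

test_that("windowed pi lies within the range of single-column pi values", {
  withr::with_seed(76, {
    rows <- vapply(1:5, function(i) rand_dna(260), "")
  })
  aln <- multi_alignment(setNames(rows, paste0("t", 1:5)))
  w <- sliding_window_pi(aln, window = 200, step = 20)
  col_pi <- vapply(seq_len(260), function(k)
    nucleotide_diversity(aln, columns = k)$pi, numeric(1))
  for (i in seq_len(nrow(w))) {
    cols <- w$start[i]:w$end[i]
    expect_gte(w$pi[i], min(col_pi[cols]) - 1e-12)
    expect_lte(w$pi[i], max(col_pi[cols]) + 1e-12)
  }
})

test_that("per-partition pi recovers rate order and extremes", {
  parts <- data.frame(gene = c("slow", "mid", "fast"),
                      length = c(900, 900, 900))
  sim <- simulate_alignment(n_taxa = 12, n_columns = 2700,
                            p_sub = c(0.02, 0.10, 0.30),
                            partitions = parts, seed = 77)
  pp <- per_partition_pi(sim$aln)
  expect_equal(pp$gene, c("slow", "mid", "fast"))
  expect_true(pp$pi[1] < pp$pi[2] && pp$pi[2] < pp$pi[3])
  expect_equal(attr(pp, "argmax"), "fast")
  expect_equal(attr(pp, "argmin"), "slow")
  # an invariant gene is the argmin with pi exactly 0
  rows <- c(t1 = paste0("AAAA", "ACGT"), t2 = paste0("AAAA", "AGGT"),
            t3 = paste0("AAAA", "ACCT"))
  aln <- multi_alignment(rows, partitions = data.frame(
    gene = c("flat", "var"), start = c(1, 5), end = c(4, 8)))
  pp2 <- per_partition_pi(aln)
  expect_equal(pp2$pi[pp2$gene == "flat"], 0)
  expect_equal(attr(pp2, "argmin"), "flat")
  # single partition spanning everything equals global pi
  aln3 <- multi_alignment(rows, partitions = data.frame(
    gene = "all", start = 1, end = 8))
  expect_equal(per_partition_pi(aln3)$pi,
               nucleotide_diversity(aln3)$pi)
})

test_that("aligned FASTA plus partition TSV round trips into an alignment", {
  withr::with_seed(78, {
    rows <- setNames(vapply(1:4, function(i) rand_dna(60), ""),
                     paste0("sp", 1:4))
  })
  fa <- tempfile(fileext = ".fa"); pt <- tempfile(fileext = ".tsv")
  write_fasta(rows, fa)
  write.table(data.frame(gene = c("g1", "g2"), start = c(1, 31),
                         end = c(30, 60)),
              pt, sep = "\t", quote = FALSE, row.names = FALSE)
  aln <- read_alignment(fa, pt)
  expect_equal(aln$taxa, paste0("sp", 1:4))
  expect_equal(nrow(per_partition_pi(aln)), 2L)
})
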