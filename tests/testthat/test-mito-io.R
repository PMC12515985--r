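# GenBank/FASTA parsing, coding-sequence extraction and gene-set
# concatenation.

test_that("GenBank coordinates, strands and labels parse as declared", {
  path <- gb_fixture(strrep("ACGT", 30),
                     c(gb_feature("CDS", "10..21", gene = "COX1")))
  g <- read_genbank(path)
  expect_s3_class(g, "mito_genome")
  expect_equal(g$topology, "circular")
  f <- g$features
  expect_equal(nrow(f), 1L)
  expect_equal(f$strand, "H")
  expect_equal(unname(f$intervals[[1]][1, ]), c(10L, 21L))

  path2 <- gb_fixture(strrep("ACGT", 30),
                      c(gb_feature("CDS", "complement(10..21)",
                                   gene = "COI")))
  f2 <- read_genbank(path2)$features
  expect_equal(f2$strand, "L")
  expect_equal(f2$gene, "COX1")   # synonym normalized
  expect_equal(unname(f2$intervals[[1]][1, ]), c(10L, 21L))
})

test_that("origin-spanning join on a circular genome extracts across the seam", {
  len <- 14135L
  withr::with_seed(11, {
    seq <- rand_dna(len)
  })
  path <- gb_fixture(seq, gb_feature("CDS", "join(14000..14135,1..100)",
                                     gene = "ND2"))
  g <- read_genbank(path)
  expect_equal(g$features$gene, "NAD2")
  ft <- feature_table(g)
  expect_equal(ft$length, 236)          # (14135-14000+1) + 100
  expect_equal(ft$n_intervals, 2L)
  # extraction concatenates the two arcs in transcription order
  expected <- paste0(substr(seq, 14000, 14135), substr(seq, 1, 100))
  expect_equal(mitocub:::feature_sequence(g, 1L), expected)
})

test_that("malformed records and out-of-bounds features are rejected", {
  bad <- tempfile(); writeLines(c("garbage", "more garbage"), bad)
  expect_error(read_genbank(bad), "LOCUS")
  path <- gb_fixture(strrep("ACGT", 10),
                     gb_feature("CDS", "30..60", gene = "COX1"))
  expect_error(read_genbank(path), "bounds")
  # ambiguity codes other than N rejected
  pathR <- gb_fixture("ACGTRACGTA", character(0))
  expect_error(read_genbank(pathR), "unsupported characters")
})

test_that("unknown gene labels downgrade to 'other' with a warning", {
  path <- gb_fixture(strrep("ACGT", 30),
                     gb_feature("CDS", "1..12", gene = "mystery9"))
  expect_warning(g <- read_genbank(path), "mystery9")
  expect_equal(g$features$gene, "other")
  expect_equal(g$features$label_raw, "mystery9")
})

test_that("FASTA reading normalizes case and U, keeps order, rejects duplicates", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">a", "acgu", ">b desc", "ACGT"), p)
  seqs <- read_fasta(p)
  expect_equal(seqs, c(a = "ACGT", b = "ACGT"))
  writeLines(c(">a", "ACGT", ">a", "ACGT"), p)
  expect_error(read_fasta(p), "duplicate")
  writeLines(character(0), p)
  expect_error(read_fasta(p))
})

test_that("stop-kind classification covers complete and incomplete tails", {
  cs <- mitocub:::classify_coding_seq("ATGAAATAA")
  expect_equal(cs$start_codon, "ATG")
  expect_equal(cs$stop_kind, "complete")
  expect_equal(cs$trimmed_nt, "ATGAAA")

  # enumerated tail cases against a hand oracle: body + {TAA, TAG, TA, T}
  body <- "ATGAAACCT"
  tails <- list(TAA = list(kind = "complete", trimmed = body),
                TAG = list(kind = "complete", trimmed = body),
                TA = list(kind = "incomplete_TA", trimmed = body),
                T = list(kind = "incomplete_T", trimmed = body))
  for (tl in names(tails)) {
    cs <- mitocub:::classify_coding_seq(paste0(body, tl))
    expect_equal(cs$stop_kind, tails[[tl]]$kind, label = tl)
    expect_equal(cs$trimmed_nt, tails[[tl]]$trimmed, label = tl)
    expect_equal(cs$stop_codon, tl)
    expect_equal(nchar(cs$trimmed_nt) %% 3, 0)
  }
  cs <- mitocub:::classify_coding_seq("ATGAAAAAAT")
  expect_equal(cs$stop_kind, "incomplete_T")
  expect_equal(cs$trimmed_nt, "ATGAAAAAA")
})

test_that("extraction reverse-complements L-strand features, matching a per-base oracle", {
  # genome segment TTATTTCAT at 4..12; its reverse complement is ATGAAATAA
  seq <- paste0("GGG", "TTATTTCAT", strrep("C", 18))
  path <- gb_fixture(seq, gb_feature("CDS", "complement(4..12)",
                                     gene = "NAD3"))
  g <- read_genbank(path)
  cs <- extract_coding_seq(g, 1L)
  expect_equal(cs$nt, "ATGAAATAA")
  expect_equal(cs$start_codon, "ATG")
  expect_equal(cs$trimmed_nt, "ATGAAA")
  # random-fixture property: L extraction == revcomp of the H slice
  withr::with_seed(5, {
    for (rep in 1:5) {
      s <- rand_dna(60)
      p <- gb_fixture(s, gb_feature("rRNA", "complement(7..36)",
                                    gene = "rrnS"))
      gg <- read_genbank(p)
      expect_equal(mitocub:::feature_sequence(gg, 1L),
                   rc_oracle(substr(s, 7, 36)))
    }
  })
})

test_that("frame errors and too-short coding sequences are caught", {
  expect_error(mitocub:::classify_coding_seq("ATGTAATTTTAA"), "internal stop")
  expect_error(mitocub:::classify_coding_seq("ATGT"), "too short")
  # length 2 mod 3 without a TA tail is unclassifiable
  expect_error(mitocub:::classify_coding_seq("ATGAAACCTGG"),
               "no recognizable")
})

test_that("gene-set concatenation preserves order, length and strand correction", {
  withr::with_seed(8, {
    t1 <- rand_dna(65); t2 <- rand_dna(70)
  })
  seq <- paste0("AA", t1, "CC", t2, "GG")
  path <- gb_fixture(seq, c(
    gb_feature("tRNA", sprintf("3..%d", 2 + 65), gene = "trnK"),
    gb_feature("tRNA", sprintf("complement(%d..%d)", 5 + 65, 4 + 65 + 70),
               gene = "trnV")))
  g <- read_genbank(path)
  cg <- concat_gene_set(g, category = "tRNA")
  expect_equal(cg$length, 135)
  expect_equal(cg$n_features, 2L)
  expect_equal(cg$sequence, paste0(t1, rc_oracle(t2)))
  expect_equal(cg$genes, c("trnK", "trnV"))
  expect_error(concat_gene_set(g, category = "rRNA"), "no features")
})

test_that("write/read round trip is identity on coordinates, strands and labels", {
  sim <- simulate_mitogenome(genome_spec(seed = 21))
  path <- tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, sim$genome$sequence)
  expect_identical(g2$topology, sim$genome$topology)
  expect_identical(g2$features$gene, sim$genome$features$gene)
  expect_identical(g2$features$category, sim$genome$features$category)
  expect_identical(g2$features$strand, sim$genome$features$strand)
  expect_identical(lapply(g2$features$intervals, unname),
                   lapply(sim$genome$features$intervals, unname))
})

test_that("FASTA round trip preserves sequences and ids", {
  seqs <- c(geneA = "ATGAAATAA", geneB = strrep("ACGT", 30))
  p <- tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  expect_equal(read_fasta(p), seqs)
})
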