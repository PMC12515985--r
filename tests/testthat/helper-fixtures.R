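# Fixtures are built in code: a minimal GenBank writer for hand-crafted
# records, plus small deterministic sequence helpers.

# write a tiny GenBank record to a temp file and return the path
gb_fixture <- function(seq, features_lines, accession = "TEST",
                       topology = "circular") {
  n <- nchar(seq)
  s <- tolower(seq)
  origin <- vapply(seq(1L, n, by = 60L), function(pos) {
    starts <- seq(pos, min(pos + 59L, n), by = 10L)
    blk <- substring(s, starts, pmin(starts + 9L, n))
    sprintf("%9d %s", pos, paste(blk, collapse = " "))
  }, character(1))
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s INV 01-JAN-2000",
            accession, n, topology),
    paste0("ACCESSION   ", accession),
    "SOURCE      test organism",
    "  ORGANISM  test organism",
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", paste0("1..", n)),
    features_lines,
    "ORIGIN",
    origin,
    "//")
  path <- tempfile(fileext = ".gb")
  writeLines(lines, path)
  path
}

gb_feature <- function(key, location, gene = NULL, product = NULL) {
  out <- sprintf("     %-16s%s", key, location)
  if (!is.null(gene)) {
    out <- c(out, sprintf('                     /gene="%s"', gene))
  }
  if (!is.null(product)) {
    out <- c(out, sprintf('                     /product="%s"', product))
  }
  out
}

# random A/C/G/T string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# hand-rolled reverse complement, independent of the package implementation
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# brute-force pairwise-deletion pi: explicit loops over pairs and columns
pi_oracle <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nr <- nrow(mat)
  ratios <- c()
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      diffs <- comp <- 0
      for (k in seq_len(ncol(mat))) {
        a <- mat[i, k]; b <- mat[j, k]
        if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
          comp <- comp + 1
          if (a != b) diffs <- diffs + 1
        }
      }
      if (comp > 0) ratios <- c(ratios, diffs / comp)
    }
  }
  mean(ratios)
}
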