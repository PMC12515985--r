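#!/usr/bin/env Rscript
# Optional validation against real deposited mitogenome records.
#
# This driver is not part of the default run: it requires GenBank flat files
# downloaded separately (e.g. via NCBI Entrez: efetch -db nuccore
# -format gb -id <accession>) into a local directory. Given such a
# directory it reruns the full comparative chain — composition, codon
# usage, PR2 and neutrality — exactly as drivers 02-04 do for the
# synthetic cohort, writing *_deposited.tsv tables for side-by-side
# comparison with published per-record statistics.
#
# Usage: Rscript analysis/06_validate_deposited.R <dir-with-gb-files>

library(mitocub)

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1L || !dir.exists(args[1])) {
  message("Usage: Rscript analysis/06_validate_deposited.R <dir-with-gb-files>")
  message("No record directory supplied; nothing to do.")
  quit(status = 0)
}

paths <- list.files(args[1], pattern = "\\.(gb|gbk|genbank)$",
                    full.names = TRUE)
stopifnot(length(paths) >= 1L)
genomes <- lapply(paths, read_genbank)
config <- run_config()
code <- genetic_code(5)
dir.create("results", showWarnings = FALSE)

comp <- do.call(rbind, lapply(genomes, dataset_composition))
num <- vapply(comp, is.numeric, TRUE)
comp[num] <- lapply(comp[num], round, 4)
write.table(comp, "results/composition_deposited.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

counts_list <- lapply(genomes, function(g)
  count_codons(coding_seqs(g, code), code, label = g$accession))
rscu <- classify_rscu(rscu_pool(counts_list, code, "mean"),
                      config$rscu_hi, config$rscu_lo)
rscu$rscu <- round(rscu$rscu, 4)
write.table(rscu, "results/rscu_deposited.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

if (length(genomes) >= 3L) {
  pos_tbl <- cohort_positional_table(genomes, code)
  write.table(cohort_pr2(pos_tbl), "results/pr2_deposited.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort_neutrality(pos_tbl, config$alpha, config$slope_cut),
              "results/neutrality_deposited.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}

message("Validated ", length(genomes), " deposited records; tables under results/")
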