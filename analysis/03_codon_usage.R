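#!/usr/bin/env Rscript
# Codon usage over the cohort: per-species RSCU with 1.6/0.6 bias classes,
# the start/stop codon census, and the two pooled RSCU tables (mean across
# species vs RSCU of summed counts — distinct statistics, both written).

library(mitocub)

paths <- list.files("results/cohort", pattern = "\\.gb$", full.names = TRUE)
stopifnot(length(paths) > 0)
genomes <- lapply(paths, read_genbank)
code <- genetic_code(5)
config <- run_config()

cds_by_species <- lapply(genomes, coding_seqs, code = code)
names(cds_by_species) <- vapply(genomes, `[[`, "", "accession")

per_species <- do.call(rbind, lapply(names(cds_by_species), function(acc) {
  cc <- count_codons(cds_by_species[[acc]], code, label = acc)
  r <- classify_rscu(compute_rscu(cc, code), config$rscu_hi, config$rscu_lo)
  cbind(species = acc, r)
}))
per_species$rscu <- round(per_species$rscu, 4)
write.table(per_species, "results/rscu_per_species.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

counts_list <- lapply(names(cds_by_species), function(acc)
  count_codons(cds_by_species[[acc]], code, label = acc))
pooled <- rbind(
  classify_rscu(rscu_pool(counts_list, code, "mean"),
                config$rscu_hi, config$rscu_lo),
  classify_rscu(rscu_pool(counts_list, code, "pooled"),
                config$rscu_hi, config$rscu_lo))
pooled$rscu <- round(pooled$rscu, 4)
pooled$count <- round(pooled$count, 2)
write.table(pooled, "results/rscu_pooled.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

census <- start_stop_census(unlist(cds_by_species, recursive = FALSE))
census_df <- rbind(
  data.frame(kind = "start", codon = names(census$starts),
             count = as.integer(census$starts)),
  data.frame(kind = "stop", codon = names(census$stops),
             count = as.integer(census$stops)))
write.table(census_df, "results/start_stop_census.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mean_r <- pooled[pooled$mode == "mean", ]
message(sprintf(
  "Cohort mean RSCU: %d overrepresented (> %.1f), %d underrepresented (< %.1f) of 62 sense codons",
  sum(mean_r$bias_class == "overrepresented"), config$rscu_hi,
  sum(mean_r$bias_class == "underrepresented"), config$rscu_lo))
message(sprintf("Start codons: %s", paste(names(census$starts),
                                          census$starts, collapse = ", ")))
message(sprintf("Stop codons:  %s", paste(names(census$stops),
                                          census$stops, collapse = ", ")))
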