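#!/usr/bin/env Rscript
# Base composition of the cohort: per-dataset (whole genome, PCGs, tRNAs,
# rRNAs) AT content and AT/GC skews, computed on the deposited (H) strand.

library(mitocub)

paths <- list.files("results/cohort", pattern = "\\.gb$", full.names = TRUE)
stopifnot(length(paths) > 0)  # run 01_simulate_cohort.R first
genomes <- lapply(paths, read_genbank)

comp <- do.call(rbind, lapply(genomes, dataset_composition))
num <- vapply(comp, is.numeric, TRUE)
comp_out <- comp
comp_out[num] <- lapply(comp_out[num], round, digits = 4)
write.table(comp_out, "results/composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

whole <- comp[comp$dataset == "whole", ]
message(sprintf(
  "Whole-genome AT%% spans %.1f..%.1f; AT skew %.3f..%.3f; GC skew %.3f..%.3f",
  min(whole$pct_AT), max(whole$pct_AT),
  min(whole$at_skew), max(whole$at_skew),
  min(whole$gc_skew), max(whole$gc_skew)))
pcg <- comp[comp$dataset == "PCGs", ]
message(sprintf("PCG dataset lengths: %d..%d bp; tRNA total %d bp; rRNA total %d bp",
                min(pcg$length), max(pcg$length),
                comp$length[comp$dataset == "tRNAs"][1],
                comp$length[comp$dataset == "rRNAs"][1]))
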