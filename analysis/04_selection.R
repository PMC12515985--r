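#!/usr/bin/env Rscript
# Mutation-pressure vs natural-selection analyses: PR2 bias-plot coordinates
# per (species, gene) and per-gene neutrality regressions (GC12 on GC3
# across the cohort) with the force classification.

library(mitocub)

paths <- list.files("results/cohort", pattern = "\\.gb$", full.names = TRUE)
stopifnot(length(paths) > 0)
genomes <- lapply(paths, read_genbank)
config <- run_config()

pos_tbl <- cohort_positional_table(genomes)
pos_out <- pos_tbl
pos_out[c("gc3", "gc12")] <- lapply(pos_out[c("gc3", "gc12")], round, 4)
write.table(pos_out, "results/positional_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pr2 <- cohort_pr2(pos_tbl)
pr2[c("x", "y")] <- lapply(pr2[c("x", "y")], round, 4)
write.table(pr2, "results/pr2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

neut <- cohort_neutrality(pos_tbl, config$alpha, config$slope_cut)
num <- vapply(neut, is.numeric, TRUE)
neut[num] <- lapply(neut[num], signif, 6)
write.table(neut, "results/neutrality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("PR2: %d/%d points right of center (G3 > C3)",
                sum(pr2$x > 0.5, na.rm = TRUE), nrow(pr2)))
tab <- table(neut$classification)
message("Neutrality classification: ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "))
message(sprintf("Slopes span %.3f..%.3f; %d/13 genes significant at alpha = %.2f",
                min(neut$slope), max(neut$slope),
                sum(neut$p_value < config$alpha), config$alpha))
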