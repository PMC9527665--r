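#!/usr/bin/env Rscript
# Generate the synthetic two-cohort editing study used by the downstream
# analysis scripts: 7 NCI + 7 AD edit-site tables, gene/repeat annotation,
# the lineage marker table, and the expression matrix with panel effects.
# Everything is written under results/sim_inputs/ in the same on-disk
# formats a real study would supply.

suppressPackageStartupMessages(library(aluedit))
dir.create("results/sim_inputs", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)  # study defaults: retention 0.5, 14 lineages
truth <- simulate_truth(cfg)
message(sprintf("simulated %d genes, %d editing sites (%.1f%% in Alu), retention %.2f",
                cfg$n_genes, nrow(truth$sites),
                100 * mean(truth$sites$in_alu), cfg$retention))

paths <- write_cohort_tables(simulate_cohorts(truth, cfg), "results/sim_inputs/tables")
message(sprintf("wrote %d control and %d case edit tables",
                length(paths$control), length(paths$case)))

write_feature_intervals(truth$features,
                        "results/sim_inputs/genes.bed",
                        "results/sim_inputs/repeats.bed")
write_marker_table(truth$markers, "results/sim_inputs/markers.csv")

expr <- simulate_expression(cfg)
write_count_matrix(expr$counts, "results/sim_inputs/counts.tsv")
write.table(data.frame(gene_id = names(expr$lengths), length = unname(expr$lengths)),
            "results/sim_inputs/gene_lengths.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(expr$panels$ISG, "results/sim_inputs/panel_isg.txt")
writeLines(expr$panels$NFKB, "results/sim_inputs/panel_nfkb.txt")
writeLines(expr$rbp_genes, "results/sim_inputs/rbp_genes.txt")
message("inputs ready under results/sim_inputs/")
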