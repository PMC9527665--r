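#!/usr/bin/env Rscript
# Per-lineage editing comparison: select lineage-defining genes by
# pct1/pct2 > 10 from the marker table, collect their per-gene editing
# indices in each cohort, and test each lineage with Welch's unpaired
# t-test (gene as the unit of observation). Output mirrors the summary-table
# layout: cell type, cohort sizes, gene count, mean +/- SEM per cohort, P,
# t, df.

suppressPackageStartupMessages(library(aluedit))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

markers <- read_marker_table("results/sim_inputs/markers.csv")
gene_sets <- select_lineage_genes(markers)
message(sprintf("%d lineages, %d marker genes selected",
                length(gene_sets), length(unlist(gene_sets))))

si_nci <- read.delim("results/analysis/site_index_NCI.tsv")
si_ad <- read.delim("results/analysis/site_index_AD.tsv")
features <- read_feature_intervals("results/sim_inputs/genes.bed",
                                   "results/sim_inputs/repeats.bed")
site_cols <- c("chrom", "pos", "strand", "edit_type")
ann <- annotate_sites(unique(rbind(si_nci[, site_cols], si_ad[, site_cols])),
                      features)
gi_nci <- gene_site_index(si_nci, ann)$genes
gi_ad <- gene_site_index(si_ad, ann)$genes

n_per_cohort <- 7
out <- lineage_editing_comparison(
  gene_sets,
  setNames(gi_nci$index, gi_nci$gene_id),
  setNames(gi_ad$index, gi_ad$gene_id),
  n_control = n_per_cohort, n_case = n_per_cohort)
write_results(out, "results/analysis/lineage_comparison.tsv")
sig <- sum(out$P < 0.05, na.rm = TRUE)
message(sprintf("%d of %d lineages significant at P < 0.05; case mean lower in %d",
                sig, nrow(out), sum(out$mean_case < out$mean_control)))
print(out[, c("cell_type", "n_genes", "mean_control", "mean_case", "P", "t", "df")],
      digits = 3)
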