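#!/usr/bin/env Rscript
# Per-gene editing indices: annotate qualifying sites, sum site indices per
# gene, keep genes with > 5 sites in either cohort and express the
# comparison as AD/NCI log2 ratios (sentinel categories where one cohort has
# no edits in the gene). Also writes the feature/Alu composition summary.

suppressPackageStartupMessages(library(aluedit))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

si_nci <- read.delim("results/analysis/site_index_NCI.tsv")
si_ad <- read.delim("results/analysis/site_index_AD.tsv")
features <- read_feature_intervals("results/sim_inputs/genes.bed",
                                   "results/sim_inputs/repeats.bed")

site_cols <- c("chrom", "pos", "strand", "edit_type")
all_sites <- unique(rbind(si_nci[, site_cols], si_ad[, site_cols]))
ann <- annotate_sites(all_sites, features)
comp <- composition_summary(ann)
message(sprintf("%.1f%% of sites in Alu elements; %.1f%% genic",
                100 * comp$alu[["Alu"]], 100 * comp$genic_fraction))
write_results(data.frame(partition = rep(c("feature", "alu"),
                                         c(length(comp$feature), length(comp$alu))),
                         class = c(names(comp$feature), names(comp$alu)),
                         fraction = c(unname(comp$feature), unname(comp$alu))),
              "results/analysis/composition.tsv")

genes <- per_gene_index(si_ad, si_nci, ann)
finite <- genes$category == "both"
message(sprintf("%d genes with > 5 sites; %.1f%% show reduced editing in AD; median AD/NCI ratio %.2f",
                nrow(genes), 100 * mean(genes$log2_ratio[finite] < 0),
                median(genes$index_case[finite] / genes$index_control[finite])))
write_results(genes, "results/analysis/gene_index.tsv")
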