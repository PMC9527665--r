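#!/usr/bin/env Rscript
# Expression screens: (i) per-sample ratio screen of RNA-binding-protein
# genes against the NCI-cohort mean with 0.5 / 2.0 cutoffs; (ii) panel-level
# log2 FPKM fold changes for the ISG and NF-kB gene sets with permutation
# p-values, BH adjustment, and a two-way (gene x cohort) ANOVA per panel.

suppressPackageStartupMessages(library(aluedit))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

counts <- read_count_matrix("results/sim_inputs/counts.tsv")
lengths <- read.delim("results/sim_inputs/gene_lengths.tsv")
cohorts <- setNames(ifelse(startsWith(colnames(counts), "NCI"), "control", "case"),
                    colnames(counts))

rbp <- readLines("results/sim_inputs/rbp_genes.txt")
scr <- ratio_screen(counts, rbp, cohorts)
write_results(scr, "results/analysis/rbp_ratio_screen.tsv")
for (g in rbp) {
  case <- scr[scr$gene == g & scr$cohort == "case", ]
  message(sprintf("%s under-expressed (ratio < 0.5) in %d of %d AD samples",
                  g, sum(case$category == "under"), nrow(case)))
}

f <- fpkm(counts, setNames(lengths$length, lengths$gene_id))
panels <- list(ISG = readLines("results/sim_inputs/panel_isg.txt"),
               NFKB = readLines("results/sim_inputs/panel_nfkb.txt"))
pfc <- panel_fold_change(f, panels, cohorts, seed = 1)
write_results(pfc, "results/analysis/panel_fold_change.tsv")
for (pn in names(panels)) {
  sub <- pfc[pfc$panel == pn, ]
  av <- panel_anova(f, panels[[pn]], cohorts)
  message(sprintf("%s: mean log2 AD/NCI ratio %.2f; %d/%d genes FDR < 0.05; cohort ANOVA P = %.2g",
                  pn, mean(sub$log2_ratio, na.rm = TRUE),
                  sum(sub$p_adj < 0.05, na.rm = TRUE), nrow(sub),
                  av$factor_b$p))
}
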