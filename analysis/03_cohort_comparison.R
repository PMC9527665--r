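#!/usr/bin/env Rscript
# Common-site analysis between the NCI and AD cohorts: sites present in all
# samples of one cohort but not all of the other, sites shared by all
# samples of both, ranked edit/read curves, and the chi-square comparison of
# site counts.

suppressPackageStartupMessages(library(aluedit))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)
fc <- filter_config()

load_presence <- function(label) {
  files <- list.files("results/sim_inputs/tables", pattern = paste0("^", label),
                      full.names = TRUE)
  build_presence(lapply(files, function(p) {
    filter_sites(read_edit_table(p, sub("\\.tsv$", "", basename(p)), label), fc)
  }))
}

pres_nci <- load_presence("NCI")
pres_ad <- load_presence("AD")
report <- common_sites(pres_nci, pres_ad)
cnt <- attr(report, "counts")
message(sprintf("present in all NCI only: %d; all AD only: %d; shared by all: %d",
                cnt[["A_only"]], cnt[["B_only"]], cnt[["shared"]]))

chi <- compare_site_counts(cnt[["A_only"]] + cnt[["shared"]],
                           cnt[["B_only"]] + cnt[["shared"]])
message(sprintf("chi-square on all-sample site counts: X2 = %.1f, P = %.3g",
                chi$statistic, chi$p))

write_results(as.data.frame(report), "results/analysis/common_sites.tsv")
write_results(data.frame(comparison = "all_sample_site_counts",
                         chi2 = chi$statistic, df = chi$df, p = chi$p),
              "results/analysis/common_sites_chi2.tsv")
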