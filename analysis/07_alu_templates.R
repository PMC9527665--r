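#!/usr/bin/env Rscript
# In-silico edited Alu template design: take an Alu-length sequence, mark a
# set of adenosines edited in the control cohort but not in the case cohort,
# substitute them A -> G as an editing mimic, and export the SP6-promoter-
# prefixed unedited/edited pair as FASTA for synthesis.

suppressPackageStartupMessages(library(aluedit))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

set.seed(1)
alu_seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                        prob = c(0.30, 0.22, 0.22, 0.26)), collapse = "")
a_pos <- which(strsplit(alu_seq, "")[[1]] == "A")
edited_pos <- sort(a_pos[sample.int(length(a_pos), 7)])  # 6-8 edited A's typical

tmpl <- design_edited_template(alu_seq, edited_pos, name = "synthetic_Alu")
write_template_fasta(tmpl, "results/analysis/alu_templates.fa")
message(sprintf("edited %d adenosines at positions %s; constructs are %d nt with the SP6 promoter",
                length(edited_pos), paste(edited_pos, collapse = ","),
                nchar(tmpl$edited_construct)))
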