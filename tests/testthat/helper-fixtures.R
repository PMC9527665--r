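# fixture builders and brute-force oracles shared across test files

# a tiny edit table from parallel vectors
make_table <- function(chrom, pos, strand, edit_type, edits, reads,
                       sample_id = "s1", cohort = "NCI") {
  edit_table(data.frame(chrom = chrom, pos = pos, strand = strand,
                        edit_type = edit_type, edits = edits, reads = reads,
                        stringsAsFactors = FALSE),
             sample_id = sample_id, cohort = cohort)
}

# a random pool of distinct sites
random_site_pool <- function(n) {
  pool <- expand.grid(chrom = c("chr1", "chr2"), pos = 1:200,
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  pool <- pool[sample.int(nrow(pool), n), ]
  pool$edit_type <- ifelse(pool$strand == "+", "AG", "TC")
  rownames(pool) <- NULL
  pool
}

# a random cohort: each sample contains a random subset of the pool with
# ratios drawn to pass the default filters
random_cohort <- function(pool, n_samples, cohort = "NCI", p_present = 0.5) {
  lapply(seq_len(n_samples), function(s) {
    keep <- runif(nrow(pool)) < p_present
    sub <- pool[keep, , drop = FALSE]
    reads <- sample(10:60, nrow(sub), replace = TRUE)
    edits <- pmax(1, rbinom(nrow(sub), reads, runif(nrow(sub), 0.1, 0.8)))
    make_table(sub$chrom, sub$pos, sub$strand, sub$edit_type, edits, reads,
               sample_id = paste0(cohort, "_", s), cohort = cohort)
  })
}

# oracle: presence by explicit nested loops over sites and samples
brute_presence <- function(tables) {
  all_sites <- unique(do.call(rbind, lapply(tables, function(t) {
    as.data.frame(t)[, c("chrom", "pos", "strand", "edit_type")]
  })))
  rows <- list()
  for (i in seq_len(nrow(all_sites))) {
    for (t in tables) {
      hit <- which(t$chrom == all_sites$chrom[i] & t$pos == all_sites$pos[i] &
                     t$strand == all_sites$strand[i] &
                     t$edit_type == all_sites$edit_type[i])
      if (length(hit)) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = all_sites$chrom[i], pos = all_sites$pos[i],
          strand = all_sites$strand[i], edit_type = all_sites$edit_type[i],
          sample_id = attr(t, "sample_id"), ratio = t$ratio[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos, out$strand, out$edit_type, out$sample_id,
            method = "radix"), , drop = FALSE]
}

# oracle: common-site sets by exhaustive per-site sample counting
brute_common_sets <- function(tables_a, tables_b, n_a, n_b) {
  keys_in <- function(t) paste(t$chrom, t$pos, t$strand, t$edit_type, sep = "|")
  all_keys <- unique(c(unlist(lapply(tables_a, keys_in)),
                       unlist(lapply(tables_b, keys_in))))
  in_all <- function(key, tables, n) {
    sum(vapply(tables, function(t) key %in% keys_in(t), NA)) == n
  }
  sets <- list(A_only = character(), B_only = character(), shared = character())
  for (key in all_keys) {
    a <- in_all(key, tables_a, n_a)
    b <- in_all(key, tables_b, n_b)
    if (a && b) sets$shared <- c(sets$shared, key)
    else if (a) sets$A_only <- c(sets$A_only, key)
    else if (b) sets$B_only <- c(sets$B_only, key)
  }
  lapply(sets, sort)
}

# drop the class and bookkeeping attributes for plain data-frame comparison
strip_attrs <- function(df) {
  attr(df, "cohort") <- NULL
  attr(df, "samples") <- NULL
  attr(df, "counts") <- NULL
  attr(df, "cohorts") <- NULL
  attr(df, "sample_id") <- NULL
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

report_keys <- function(report, set) {
  sub <- report[report$set == set, ]
  sort(paste(sub$chrom, sub$pos, sub$strand, sub$edit_type, sep = "|"))
}

# per-lineage Welch p-values for one simulated cohort draw; the site layout
# (truth) is held fixed and only the sequencing draw varies with cohort_seed,
# so replicate runs probe the sampling-noise null efficiently
lineage_pvals_once <- function(truth, cfg, cohort_seed) {
  cfg$seed <- cohort_seed
  coh <- simulate_cohorts(truth, cfg)
  fc <- filter_config()
  pres_c <- build_presence(lapply(coh$control, filter_sites, fc))
  pres_k <- build_presence(lapply(coh$case, filter_sites, fc))
  ann <- truth$sites[, c("chrom", "pos", "strand", "edit_type", "gene_id",
                         "feature_class", "in_alu")]
  gi_c <- gene_site_index(site_index(pres_c, fc), ann)$genes
  gi_k <- gene_site_index(site_index(pres_k, fc), ann)$genes
  sets <- select_lineage_genes(truth$markers)
  lineage_editing_comparison(
    sets, setNames(gi_c$index, gi_c$gene_id), setNames(gi_k$index, gi_k$gene_id),
    cfg$n_control, cfg$n_case)
}

# a small fully in-memory feature set for annotation tests
toy_features <- function() {
  structure(list(
    genes = data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
      start = c(101L, 101L, 501L, 451L, 101L),
      end = c(1000L, 400L, 1000L, 600L, 500L),
      gene_id = c("GA", "GA", "GA", "GB", "GC"),
      feature_class = c("intron", "5UTR", "3UTR", "3UTR", "ncRNA"),
      strand = c("+", "+", "+", "-", "+"), stringsAsFactors = FALSE),
    repeats = data.frame(
      chrom = c("chr1", "chr2"), start = c(201L, 301L), end = c(350L, 400L),
      repeat_name = c("AluSg4", "L1M"), repeat_family = c("Alu", "L1"),
      strand = c("+", "+"), stringsAsFactors = FALSE)),
    class = "feature_intervals")
}
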