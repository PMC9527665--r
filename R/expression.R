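#' FPKM normalization
#'
#' fpkm = counts * 1e9 / (gene length in bases * per-sample total mapped
#' reads).
#'
#' @param counts gene-by-sample count matrix.
#' @param gene_lengths named (or row-aligned) vector of gene lengths in
#'   bases, all > 0.
#' @param totals per-sample library sizes; defaults to column sums of
#'   `counts`. All must be > 0.
#' @return Matrix of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts)) fail("fpkm: gene length vector does not match matrix rows")
  if (any(is.na(gene_lengths) | gene_lengths <= 0)) fail("fpkm: gene lengths must be positive")
  if (length(totals) != ncol(counts)) fail("fpkm: totals do not match matrix columns")
  if (any(totals <= 0)) fail("fpkm: zero library size")
  sweep(counts / gene_lengths, 2, totals, "/") * 1e9
}

# internal: validate and split a cohort map into control/case sample ids
split_cohorts <- function(mat, cohorts) {
  if (is.null(names(cohorts))) fail("cohort map must be a named vector (sample -> cohort)")
  missing <- setdiff(names(cohorts), colnames(mat))
  if (length(missing)) fail("samples absent from matrix: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(cohorts), c("control", "case"))
  if (length(bad)) fail("cohort labels must be 'control'/'case', got: ", paste(bad, collapse = ", "))
  list(control = names(cohorts)[cohorts == "control"],
       case = names(cohorts)[cohorts == "case"])
}

#' Per-sample expression ratio screen
#'
#' For each screened gene, every sample's expression value is divided by the
#' mean expression of that gene across the control cohort. Ratios strictly
#' below `cutoff_low` are categorized `under`, strictly above `cutoff_high`
#' `over`, otherwise `normal` -- the per-sample readout used to ask, e.g.,
#' whether an RNA-binding protein is under-expressed in some but not all
#' case samples. Genes whose control mean is 0 are flagged unevaluable
#' rather than dropped.
#'
#' @param expr gene-by-sample expression matrix (counts or FPKM).
#' @param genes genes to screen (must be rows of `expr`).
#' @param cohorts named vector mapping sample ids to `"control"`/`"case"`.
#' @param cutoff_low,cutoff_high category cutoffs (defaults 0.5 and 2.0).
#' @return Data frame with columns gene, sample, cohort, value,
#'   control_mean, ratio, category (`under`/`normal`/`over`/`unevaluable`).
#' @export
ratio_screen <- function(expr, genes, cohorts, cutoff_low = 0.5, cutoff_high = 2.0) {
  grp <- split_cohorts(expr, cohorts)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) fail("ratio_screen: genes absent from matrix: ", paste(missing, collapse = ", "))
  samples <- names(cohorts)
  sub <- expr[genes, samples, drop = FALSE]
  ctrl_mean <- rowMeans(expr[genes, grp$control, drop = FALSE])
  out <- data.frame(gene = rep(genes, times = length(samples)),
                    sample = rep(samples, each = length(genes)),
                    cohort = rep(unname(cohorts[samples]), each = length(genes)),
                    value = as.vector(sub),
                    control_mean = rep(unname(ctrl_mean), times = length(samples)),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$control_mean > 0, out$value / out$control_mean, NA_real_)
  out$category <- ifelse(out$control_mean == 0, "unevaluable",
                  ifelse(out$ratio < cutoff_low, "under",
                  ifelse(out$ratio > cutoff_high, "over", "normal")))
  out
}

#' Panel-level log2 fold changes with permutation p-values
#'
#' For every gene of each panel, computes the log2 ratio of case-cohort mean
#' to control-cohort mean expression (FPKM recommended) with a delta-method
#' standard error, a two-sided Monte-Carlo label-permutation p-value (the
#' permuted statistic is the difference of cohort means, which orders
#' identically to the mean ratio and stays finite under permutation), and
#' Benjamini-Hochberg adjustment across each panel's genes. Genes absent
#' from the matrix are listed with `missing = TRUE`.
#'
#' @param expr gene-by-sample expression matrix.
#' @param panels named list of character vectors of gene ids (e.g.
#'   `list(ISG = ..., NFKB = ...)`).
#' @param cohorts named vector mapping sample ids to `"control"`/`"case"`.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return Data frame with columns panel, gene, mean_control, mean_case,
#'   log2_ratio, se, p, p_adj, fdr_flag (TRUE when adjusted p > 0.05),
#'   missing.
#' @export
panel_fold_change <- function(expr, panels, cohorts, n_perm = 10000, seed = 1) {
  grp <- split_cohorts(expr, cohorts)
  nc <- length(grp$control); nk <- length(grp$case)
  all_genes <- unlist(panels, use.names = FALSE)
  present <- intersect(all_genes, rownames(expr))
  # one set of permuted label assignments shared by all genes
  set.seed(seed)
  samples <- c(grp$control, grp$case)
  perm_idx <- replicate(n_perm, sample(length(samples)))
  sub <- expr[present, samples, drop = FALSE]
  obs_ctrl <- rowMeans(sub[, seq_len(nc), drop = FALSE])
  obs_case <- rowMeans(sub[, nc + seq_len(nk), drop = FALSE])
  obs_diff <- obs_case - obs_ctrl
  exceed <- rep(0L, length(present))
  for (b in seq_len(n_perm)) {
    pm <- sub[, perm_idx[, b], drop = FALSE]
    d <- rowMeans(pm[, nc + seq_len(nk), drop = FALSE]) -
      rowMeans(pm[, seq_len(nc), drop = FALSE])
    exceed <- exceed + (abs(d) >= abs(obs_diff) - 1e-12)
  }
  p_perm <- (exceed + 1) / (n_perm + 1)
  names(p_perm) <- present
  var_ctrl <- apply(sub[, seq_len(nc), drop = FALSE], 1, stats::var)
  var_case <- apply(sub[, nc + seq_len(nk), drop = FALSE], 1, stats::var)

  rows <- lapply(names(panels), function(pn) {
    genes <- panels[[pn]]
    here <- genes %in% present
    mc <- ifelse(here, obs_ctrl[genes], NA_real_)
    mk <- ifelse(here, obs_case[genes], NA_real_)
    l2 <- ifelse(here & mc > 0 & mk > 0, log2(mk / mc), NA_real_)
    # delta method on log2(mean_case/mean_control)
    se <- ifelse(here & mc > 0 & mk > 0,
                 sqrt(var_case[genes] / (nk * mk^2) +
                        var_ctrl[genes] / (nc * mc^2)) / log(2),
                 NA_real_)
    p <- ifelse(here, p_perm[genes], NA_real_)
    data.frame(panel = pn, gene = genes, mean_control = unname(mc),
               mean_case = unname(mk), log2_ratio = unname(l2),
               se = unname(se), p = unname(p),
               p_adj = unname(bh_adjust(p)),
               missing = !here, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_flag <- !is.na(out$p_adj) & out$p_adj > 0.05
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA over a gene panel
#'
#' Tests cohort and gene effects on log-scale expression of a panel's genes:
#' response log2(value + 1), factors gene and cohort, balanced two-way
#' ANOVA (requires equal cohort sizes). The cohort factor's F and p are the
#' panel-level significance readout.
#'
#' @param expr gene-by-sample expression matrix (FPKM recommended).
#' @param genes panel gene ids (>= 2 present in the matrix).
#' @param cohorts named vector mapping sample ids to `"control"`/`"case"`.
#' @return The [anova_two_way()] result list; `factor_a` is the gene effect,
#'   `factor_b` the cohort effect.
#' @export
panel_anova <- function(expr, genes, cohorts) {
  grp <- split_cohorts(expr, cohorts)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2) fail("panel_anova: need >= 2 panel genes present")
  samples <- names(cohorts)
  sub <- expr[genes, samples, drop = FALSE]
  resp <- log2(as.vector(sub) + 1)
  gene_f <- rep(genes, times = length(samples))
  cohort_f <- rep(unname(cohorts[samples]), each = length(genes))
  anova_two_way(resp, gene_f, cohort_f)
}
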