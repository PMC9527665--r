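#' Select lineage-defining genes by pct1/pct2 ratio
#'
#' A gene defines a cell lineage when the fraction of cells expressing it
#' inside the lineage's cluster (pct1) exceeds the fraction in all other
#' clusters (pct2) by more than `ratio_threshold_exclusive`-fold. A gene
#' detected only inside the cluster (pct2 = 0, pct1 > 0) has an infinite
#' ratio and is selected.
#'
#' @param markers data frame with columns gene, cluster, pct1, pct2 (see
#'   [read_marker_table()]).
#' @param ratio_threshold_exclusive genes selected when pct1/pct2 is
#'   strictly above this (default 10).
#' @return Named list: one character vector of gene ids per cluster.
#' @export
select_lineage_genes <- function(markers, ratio_threshold_exclusive = 10) {
  if (!nrow(markers)) fail("select_lineage_genes: empty marker table")
  if (any(markers$pct1 < 0 | markers$pct1 > 1 | markers$pct2 < 0 | markers$pct2 > 1)) {
    fail("select_lineage_genes: pct values must lie in [0, 1]")
  }
  ratio <- ifelse(markers$pct2 == 0,
                  ifelse(markers$pct1 > 0, Inf, 0),
                  markers$pct1 / markers$pct2)
  sel <- markers[ratio > ratio_threshold_exclusive, , drop = FALSE]
  clusters <- sort(unique(markers$cluster))
  out <- lapply(clusters, function(cl) sort(unique(sel$gene[sel$cluster == cl])))
  names(out) <- clusters
  out
}

#' Compare per-lineage editing indices between cohorts
#'
#' For each lineage, the unit of observation is the gene: the vectors of
#' per-gene editing indices of the lineage-defining genes in the control and
#' case cohorts are compared with Welch's unpaired t-test. Genes without any
#' qualifying editing site in a cohort contribute index 0 there (they are
#' not dropped, so uniform editing loss is not masked by asymmetric gene
#' removal). Lineages with fewer than 3 genes are flagged untestable.
#'
#' @param gene_sets named list of gene-id vectors per lineage, from
#'   [select_lineage_genes()].
#' @param index_control,index_case named numeric vectors of per-gene editing
#'   indices (e.g. from [gene_site_index()]`$genes`, as
#'   `setNames(index, gene_id)`); missing genes count as 0.
#' @param n_control,n_case numbers of samples in each cohort (reported
#'   alongside the per-gene statistics).
#' @return Data frame with one row per lineage: cell_type, n_control,
#'   n_case, n_genes, mean_control, sem_control, mean_case, sem_case, P, t,
#'   df, untestable.
#' @export
lineage_editing_comparison <- function(gene_sets, index_control, index_case,
                                       n_control, n_case) {
  if (!length(gene_sets)) fail("lineage_editing_comparison: no lineages")
  rows <- lapply(names(gene_sets), function(lin) {
    genes <- gene_sets[[lin]]
    ctrl <- unname(index_control[genes]); ctrl[is.na(ctrl)] <- 0
    case <- unname(index_case[genes]); case[is.na(case)] <- 0
    base <- data.frame(cell_type = lin, n_control = n_control, n_case = n_case,
                       n_genes = length(genes), stringsAsFactors = FALSE)
    test <- NULL
    untestable <- length(genes) < 3
    if (!untestable) {
      test <- tryCatch(welch_t(ctrl, case), error = function(e) NULL)
      if (is.null(test)) untestable <- TRUE
    }
    base$mean_control <- if (length(genes)) mean(ctrl) else NA_real_
    base$sem_control <- if (length(genes) > 1) sem(ctrl) else NA_real_
    base$mean_case <- if (length(genes)) mean(case) else NA_real_
    base$sem_case <- if (length(genes) > 1) sem(case) else NA_real_
    base$P <- if (untestable) NA_real_ else test$p
    base$t <- if (untestable) NA_real_ else test$statistic
    base$df <- if (untestable) NA_real_ else test$df
    base$untestable <- untestable
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
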