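#' Per-site editing index within a cohort
#'
#' For every site present (after filtering) in at least
#' `cfg$min_samples_inclusive` samples of the cohort, computes the mean
#' edit/read ratio over the samples containing the site and the editing
#' index: mean ratio multiplied by the number of samples with edits at the
#' site. Sites present in fewer samples are omitted. With the default
#' thresholds (ratio > 0.05, >= 2 samples) every emitted index exceeds 0.1,
#' the analytic floor returned by [site_index_floor()].
#'
#' @param pres a [build_presence()] matrix.
#' @param cfg a [filter_config()] (only `min_samples_inclusive` is used here;
#'   the read/ratio thresholds are assumed already applied).
#' @return Data frame with columns cohort, chrom, pos, strand, edit_type,
#'   n_samples, mean_ratio, index, ordered by site.
#' @export
site_index <- function(pres, cfg = filter_config()) {
  cohort <- attr(pres, "cohort")
  empty <- data.frame(cohort = character(), chrom = character(), pos = integer(),
                      strand = character(), edit_type = character(),
                      n_samples = integer(), mean_ratio = numeric(),
                      index = numeric())
  if (!nrow(pres)) return(empty)
  key <- site_key(pres)
  n <- tapply(pres$ratio, key, length)
  mr <- tapply(pres$ratio, key, mean)
  keep <- n >= cfg$min_samples_inclusive
  if (!any(keep)) return(empty)
  keys <- names(n)[keep]
  m <- matrix(unlist(strsplit(keys, "|", fixed = TRUE)), ncol = 4, byrow = TRUE)
  out <- data.frame(cohort = cohort, chrom = m[, 1], pos = as.integer(m[, 2]),
                    strand = m[, 3], edit_type = m[, 4],
                    n_samples = as.integer(n[keep]),
                    mean_ratio = as.numeric(mr[keep]),
                    index = as.numeric(mr[keep]) * as.integer(n[keep]),
                    stringsAsFactors = FALSE)
  out <- out[site_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analytic floor of the per-site editing index
#'
#' Under the inclusion rules every admitted per-sample ratio is strictly
#' greater than `min_ratio_exclusive` and a site needs at least
#' `min_samples_inclusive` samples, so the per-site index (mean ratio x
#' number of samples) is bounded below by their product -- 0.1 with the
#' default thresholds, matching the observed lower end of genome-wide
#' index-per-site distributions. The bound is an infimum: approached in the
#' limit, never attained.
#'
#' @param cfg a [filter_config()].
#' @return The infimum, `min_ratio_exclusive * min_samples_inclusive`.
#' @export
site_index_floor <- function(cfg = filter_config()) {
  cfg$min_ratio_exclusive * cfg$min_samples_inclusive
}

#' Genome-wide editing index for one cohort
#'
#' The genome-wide index is the sum of per-site indices (equivalently, the
#' summed edit/read ratios over all qualifying site-sample observations).
#' Sites are returned ranked by descending index with deterministic
#' tie-breaking.
#'
#' @param records output of [site_index()] for one cohort.
#' @return List with `total` (the summed index) and `ranked` (the records
#'   ordered by descending index, with a `rank` column).
#' @export
genome_wide_index <- function(records) {
  if (length(unique(records$cohort)) > 1) {
    fail("genome_wide_index: records span multiple cohorts")
  }
  if (!nrow(records)) {
    records$rank <- integer()
    return(list(total = 0, ranked = records))
  }
  o <- order(-records$index, records$chrom, records$pos, records$strand,
             method = "radix")
  ranked <- records[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  list(total = sum(records$index), ranked = ranked)
}

#' Per-gene editing index for one cohort
#'
#' Sums per-site indices over the sites assigned to each gene by the
#' annotation. Intergenic sites (no gene) are excluded and their summed
#' index reported separately.
#'
#' @param records output of [site_index()] for one cohort.
#' @param annotations output of [annotate_sites()] covering the records'
#'   sites.
#' @return List with `genes` (data frame: gene_id, n_sites, index) and
#'   `intergenic_index` (summed index of unassigned sites).
#' @export
gene_site_index <- function(records, annotations) {
  ann_key <- site_key(annotations)
  rec_key <- site_key(records)
  idx <- match(rec_key, ann_key)
  if (anyNA(idx)) fail("gene_site_index: ", sum(is.na(idx)), " sites lack annotations")
  gene <- annotations$gene_id[idx]
  intergenic <- is.na(gene)
  genic <- records[!intergenic, , drop = FALSE]
  gene <- gene[!intergenic]
  if (!nrow(genic)) {
    genes <- data.frame(gene_id = character(), n_sites = integer(), index = numeric())
  } else {
    n <- tapply(genic$index, gene, length)
    s <- tapply(genic$index, gene, sum)
    genes <- data.frame(gene_id = names(n), n_sites = as.integer(n),
                        index = as.numeric(s), stringsAsFactors = FALSE)
    genes <- genes[order(genes$gene_id, method = "radix"), , drop = FALSE]
    rownames(genes) <- NULL
  }
  list(genes = genes, intergenic_index = sum(records$index[intergenic]))
}

#' Case/control per-gene editing index comparison
#'
#' Joins per-gene indices of a case and a control cohort, keeps genes with
#' strictly more than `min_sites_per_gene_exclusive` editing sites in either
#' cohort, and expresses the comparison as log2(case index / control index).
#' A gene with index 0 in one cohort (no qualifying edits) gets a sentinel
#' category instead of a finite ratio: `case_only`, `control_only`, or
#' `both_zero`.
#'
#' @param records_case,records_control [site_index()] outputs for the two
#'   cohorts.
#' @param annotations output of [annotate_sites()] covering all sites.
#' @param min_sites_per_gene_exclusive genes qualify with strictly more
#'   sites than this in either cohort (default 5).
#' @return Data frame with columns gene_id, n_sites_case, n_sites_control,
#'   index_case, index_control, log2_ratio, category (one of `both`,
#'   `case_only`, `control_only`, `both_zero`).
#' @export
per_gene_index <- function(records_case, records_control, annotations,
                           min_sites_per_gene_exclusive = 5) {
  gc <- gene_site_index(records_case, annotations)$genes
  gn <- gene_site_index(records_control, annotations)$genes
  genes <- sort(union(gc$gene_id, gn$gene_id))
  ic <- gc$index[match(genes, gc$gene_id)]; ic[is.na(ic)] <- 0
  nc <- gc$n_sites[match(genes, gc$gene_id)]; nc[is.na(nc)] <- 0L
  io <- gn$index[match(genes, gn$gene_id)]; io[is.na(io)] <- 0
  no <- gn$n_sites[match(genes, gn$gene_id)]; no[is.na(no)] <- 0L
  keep <- nc > min_sites_per_gene_exclusive | no > min_sites_per_gene_exclusive
  out <- data.frame(gene_id = genes, n_sites_case = nc, n_sites_control = no,
                    index_case = ic, index_control = io,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$log2_ratio <- ifelse(out$index_case > 0 & out$index_control > 0,
                           log2(out$index_case / out$index_control), NA_real_)
  out$category <- ifelse(out$index_case > 0 & out$index_control > 0, "both",
                  ifelse(out$index_case > 0, "case_only",
                  ifelse(out$index_control > 0, "control_only", "both_zero")))
  out <- out[order(out$log2_ratio, out$gene_id, method = "radix",
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
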