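#' Common-site sets between two cohorts
#'
#' Classifies editing sites by cohort-wide presence: `A_only` sites are
#' present in every sample of cohort A but not in every sample of cohort B
#' (including sites absent from B entirely), `B_only` is symmetric, and
#' `shared` sites are present in every sample of both cohorts. Per-site mean
#' edit/read ratios are computed within each cohort over the samples
#' containing the site (NA when the cohort has none).
#'
#' @param pres_a,pres_b [build_presence()] matrices for the two cohorts.
#' @param n_a,n_b cohort sizes (defaults: number of samples recorded in each
#'   presence matrix).
#' @return A `common_site_report`: data frame with columns set, chrom, pos,
#'   strand, edit_type, mean_ratio_A, mean_ratio_B, rank (rank within set by
#'   the defining cohort's mean ratio, descending; shared sites ranked by
#'   cohort A). Attributes `counts` (named vector of set sizes) and
#'   `cohorts`.
#' @export
common_sites <- function(pres_a, pres_b,
                         n_a = length(attr(pres_a, "samples")),
                         n_b = length(attr(pres_b, "samples"))) {
  if (n_a < 1 || n_b < 1) fail("common_sites: cohort sizes must be >= 1")
  cnt_a <- presence_counts(pres_a)
  cnt_b <- presence_counts(pres_b)
  all_a <- names(cnt_a)[cnt_a == n_a]
  all_b <- names(cnt_b)[cnt_b == n_b]
  shared <- intersect(all_a, all_b)
  a_only <- setdiff(all_a, all_b)
  b_only <- setdiff(all_b, all_a)
  mean_by_key <- function(pres, keys) {
    if (!length(keys)) return(numeric())
    sub <- pres[site_key(pres) %in% keys, , drop = FALSE]
    tapply(sub$ratio, site_key(sub), mean)[keys]
  }
  key_fields <- function(keys) {
    if (!length(keys)) {
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), edit_type = character()))
    }
    m <- matrix(unlist(strsplit(keys, "|", fixed = TRUE)), ncol = 4, byrow = TRUE)
    data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), strand = m[, 3],
               edit_type = m[, 4], stringsAsFactors = FALSE)
  }
  one_set <- function(keys, set_name, ranking_cohort) {
    df <- key_fields(keys)
    df$set <- rep(set_name, length(keys))
    df$mean_ratio_A <- if (length(keys)) unname(mean_by_key(pres_a, keys)) else numeric()
    df$mean_ratio_B <- if (length(keys)) unname(mean_by_key(pres_b, keys)) else numeric()
    by <- if (ranking_cohort == "A") df$mean_ratio_A else df$mean_ratio_B
    df <- rank_by_ratio(df, ratios = by)
    df
  }
  out <- rbind(one_set(a_only, "A_only", "A"),
               one_set(b_only, "B_only", "B"),
               one_set(shared, "shared", "A"))
  out <- out[, c("set", "chrom", "pos", "strand", "edit_type",
                 "mean_ratio_A", "mean_ratio_B", "rank")]
  rownames(out) <- NULL
  structure(out,
            counts = c(A_only = length(a_only), B_only = length(b_only),
                       shared = length(shared)),
            cohorts = c(A = attr(pres_a, "cohort"), B = attr(pres_b, "cohort")),
            class = c("common_site_report", "data.frame"))
}

#' Rank sites by mean edit/read ratio
#'
#' Orders sites by descending ratio; ties are broken by (chrom, pos, strand)
#' so the ranking is deterministic. Adds a 1-based `rank` column.
#'
#' @param sites data frame with site columns and a ratio column.
#' @param ratios numeric vector of ratios to rank by (default column
#'   `mean_ratio` or `ratio`).
#' @return `sites` reordered, with a `rank` column.
#' @export
rank_by_ratio <- function(sites, ratios = NULL) {
  if (is.null(ratios)) ratios <- sites$mean_ratio %||% sites$ratio
  if (!nrow(sites)) {
    sites$rank <- integer()
    return(sites)
  }
  o <- order(-ratios, sites$chrom, sites$pos, sites$strand, method = "radix")
  out <- sites[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare editing-site counts between two cohorts
#'
#' Two-cell chi-square goodness-of-fit test of the observed site counts
#' against equal expected counts, df = 1. Symmetric in its arguments.
#'
#' @param count_a,count_b non-negative site counts; their sum must be
#'   positive.
#' @return An `edit_test`.
#' @export
compare_site_counts <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0) fail("compare_site_counts: counts must be non-negative")
  if (count_a + count_b == 0) fail("compare_site_counts: both counts are zero")
  chi2_gof(c(count_a, count_b))
}
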