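#' Site-inclusion filter configuration
#'
#' Thresholds used to admit an editing site into the analysis: total reads
#' strictly greater than `min_reads_exclusive`, edit/read ratio strictly
#' greater than `min_ratio_exclusive`, and (downstream, for index
#' computation) presence in at least `min_samples_inclusive` samples of a
#' cohort. Defaults are reads > 5, ratio > 0.05, >= 2 samples.
#'
#' @param min_reads_exclusive sites need total reads strictly above this.
#' @param min_ratio_exclusive sites need edit/read ratio strictly above this.
#' @param min_samples_inclusive sites need at least this many samples.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_reads_exclusive = 5,
                          min_ratio_exclusive = 0.05,
                          min_samples_inclusive = 2) {
  if (!is_count(min_reads_exclusive) || min_reads_exclusive < 0) {
    fail("filter_config: min_reads_exclusive must be an integer >= 0")
  }
  if (!is.numeric(min_ratio_exclusive) || min_ratio_exclusive < 0 ||
      min_ratio_exclusive >= 1) {
    fail("filter_config: min_ratio_exclusive must lie in [0, 1)")
  }
  if (!is_count(min_samples_inclusive) || min_samples_inclusive < 1) {
    fail("filter_config: min_samples_inclusive must be an integer >= 1")
  }
  structure(list(min_reads_exclusive = as.integer(min_reads_exclusive),
                 min_ratio_exclusive = as.numeric(min_ratio_exclusive),
                 min_samples_inclusive = as.integer(min_samples_inclusive)),
            class = "filter_config")
}

#' Apply site-inclusion thresholds to one sample's edit table
#'
#' Retains sites with `reads > min_reads_exclusive` and
#' `ratio > min_ratio_exclusive` (strict inequalities). Idempotent; a site
#' failing either threshold is treated as absent from the sample everywhere
#' downstream.
#'
#' @param table an [edit_table()].
#' @param cfg a [filter_config()].
#' @return The filtered [edit_table()].
#' @export
filter_sites <- function(table, cfg = filter_config()) {
  keep <- table$reads > cfg$min_reads_exclusive &
    table$ratio > cfg$min_ratio_exclusive
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            sample_id = attr(table, "sample_id"),
            cohort = attr(table, "cohort"),
            class = class(table))
}

#' Build the per-cohort site presence matrix
#'
#' Records, for every site observed anywhere in the cohort after filtering,
#' which samples contain it and at what edit/read ratio. Long format: one row
#' per (site, sample) occurrence.
#'
#' @param cohort a list of filtered [edit_table()] objects sharing one cohort
#'   label.
#' @return A `presence_matrix`: data frame with columns chrom, pos, strand,
#'   edit_type, sample_id, ratio; attributes `cohort`, `samples` (all sample
#'   ids in the cohort, including those contributing no sites).
#' @export
build_presence <- function(cohort) {
  if (!length(cohort)) fail("build_presence: empty cohort")
  labels <- unname(vapply(cohort, function(t) attr(t, "cohort") %||% NA_character_, ""))
  if (length(unique(labels)) != 1 || anyNA(labels)) {
    fail("build_presence: tables carry mixed or missing cohort labels")
  }
  ids <- unname(vapply(cohort, function(t) attr(t, "sample_id") %||% NA_character_, ""))
  if (anyDuplicated(ids)) fail("build_presence: duplicate sample ids")
  rows <- lapply(seq_along(cohort), function(i) {
    t <- cohort[[i]]
    if (!nrow(t)) return(NULL)
    data.frame(chrom = t$chrom, pos = t$pos, strand = t$strand,
               edit_type = t$edit_type, sample_id = ids[i], ratio = t$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      edit_type = character(), sample_id = character(),
                      ratio = numeric())
  }
  out <- out[order(out$chrom, out$pos, out$strand, out$edit_type, out$sample_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, cohort = labels[1], samples = ids,
            class = c("presence_matrix", "data.frame"))
}

# internal: per-site sample counts of a presence matrix, as a named integer
# vector keyed by site key
presence_counts <- function(pres) {
  if (!nrow(pres)) return(integer())
  tab <- table(site_key(pres))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
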