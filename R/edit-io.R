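#' Construct a per-sample edit-site table
#'
#' An `edit_table` is a data frame of called A-to-I editing events for one
#' sample, one row per genomic site, carrying the sample id and cohort label
#' as attributes. Positions are 1-based; `ratio` is `edits/reads`.
#'
#' @param df data frame with columns `chrom`, `pos`, `strand`, `edit_type`,
#'   `edits`, `reads` (and optionally `ratio`, which is recomputed).
#' @param sample_id sample identifier.
#' @param cohort cohort label (e.g. `"NCI"`, `"AD"`).
#' @return An `edit_table` (data frame subclass).
#' @export
edit_table <- function(df, sample_id, cohort) {
  required <- c("chrom", "pos", "strand", "edit_type", "edits", "reads")
  missing <- setdiff(required, names(df))
  if (length(missing)) fail("edit_table: missing columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, required]
  if (nrow(df)) {
    if (any(df$pos < 1)) fail("edit_table: positions must be >= 1")
    if (!all(df$strand %in% c("+", "-"))) fail("edit_table: strand must be '+' or '-'")
    if (any(df$reads < 1)) fail("edit_table: total reads must be >= 1")
    if (any(df$edits < 0)) fail("edit_table: edit counts must be >= 0")
    if (any(df$edits > df$reads)) fail("edit_table: edits exceed reads")
    if (anyDuplicated(site_key(df))) fail("edit_table: duplicate site key in sample '", sample_id, "'")
  }
  df$ratio <- ifelse(df$reads > 0, df$edits / df$reads, NA_real_)
  df <- df[site_order(df), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            sample_id = as.character(sample_id),
            cohort = as.character(cohort),
            class = c("edit_table", "data.frame"))
}

#' Read an edit-site table in the caller dialect
#'
#' The dialect is six tab-separated columns: chromosome, 0-based start,
#' 1-based end, two-letter edit type (e.g. `AG` for A-to-G), strand, and
#' `edits:reads`. Lines starting with `#` are treated as headers and skipped.
#' Each row describes one single-base site; the 1-based position is the `end`
#' column.
#'
#' @param path path to the table.
#' @param sample_id sample identifier to attach.
#' @param cohort cohort label to attach.
#' @return An [edit_table()].
#' @export
read_edit_table <- function(path, sample_id, cohort) {
  if (!file.exists(path)) fail("read_edit_table: no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(edit_table(data.frame(chrom = character(), pos = integer(),
                                 strand = character(), edit_type = character(),
                                 edits = integer(), reads = integer()),
                      sample_id, cohort))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6)) {
    bad <- idx[which(nfield != 6)[1]]
    fail("read_edit_table: line ", bad, ": expected 6 tab-separated fields, got ",
         nfield[which(nfield != 6)[1]])
  }
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end1 <- suppressWarnings(as.integer(m[, 3]))
  counts <- strsplit(m[, 6], ":", fixed = TRUE)
  if (any(lengths(counts) != 2)) {
    bad <- idx[which(lengths(counts) != 2)[1]]
    fail("read_edit_table: line ", bad, ": count field must be 'edits:reads'")
  }
  cm <- matrix(unlist(counts), ncol = 2, byrow = TRUE)
  edits <- suppressWarnings(as.integer(cm[, 1]))
  reads <- suppressWarnings(as.integer(cm[, 2]))
  bad_num <- which(is.na(start0) | is.na(end1) | is.na(edits) | is.na(reads))
  if (length(bad_num)) fail("read_edit_table: line ", idx[bad_num[1]], ": non-integer numeric field")
  if (any(end1 != start0 + 1L)) {
    bad <- which(end1 != start0 + 1L)[1]
    fail("read_edit_table: line ", idx[bad], ": not a single-base interval (end != start + 1)")
  }
  bad_type <- which(!grepl("^[ACGT]{2}$", m[, 4]))
  if (length(bad_type)) fail("read_edit_table: line ", idx[bad_type[1]], ": bad edit type '", m[bad_type[1], 4], "'")
  bad_strand <- which(!m[, 5] %in% c("+", "-"))
  if (length(bad_strand)) fail("read_edit_table: line ", idx[bad_strand[1]], ": bad strand '", m[bad_strand[1], 5], "'")
  bad_cnt <- which(edits > reads | reads < 1 | edits < 0)
  if (length(bad_cnt)) {
    fail("read_edit_table: line ", idx[bad_cnt[1]], ": invalid counts ",
         edits[bad_cnt[1]], ":", reads[bad_cnt[1]])
  }
  df <- data.frame(chrom = m[, 1], pos = end1, strand = m[, 5],
                   edit_type = m[, 4], edits = edits, reads = reads,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(site_key(df))) {
    dup <- which(duplicated(site_key(df)))[1]
    fail("read_edit_table: duplicate site at ", df$chrom[dup], ":", df$pos[dup])
  }
  edit_table(df, sample_id, cohort)
}

#' Write an edit-site table in the caller dialect
#'
#' Inverse of [read_edit_table()]: positions are written back as 0-based
#' start / 1-based end, counts as `edits:reads`.
#'
#' @param tab an [edit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edit_table <- function(tab, path) {
  lines <- c("#chrom\tstart\tend\ttype\tstrand\tedits:reads",
             if (nrow(tab)) {
               paste(tab$chrom, tab$pos - 1L, tab$pos, tab$edit_type, tab$strand,
                     paste0(tab$edits, ":", tab$reads), sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}

# internal: parse one BED6-like file.  On disk intervals are 0-based
# half-open; internally 1-based inclusive.
read_bed6 <- function(path, what) {
  if (!file.exists(path)) fail("read_feature_intervals: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), extra = character(), strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 6)) fail("read_feature_intervals: ", what, ": expected 6 columns")
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  start0 <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  if (any(is.na(start0) | is.na(end))) fail("read_feature_intervals: ", what, ": non-integer coordinates")
  if (any(start0 >= end)) fail("read_feature_intervals: ", what, ": start >= end")
  data.frame(chrom = m[, 1], start = start0 + 1L, end = end,
             name = m[, 4], extra = m[, 5], strand = m[, 6],
             stringsAsFactors = FALSE)
}

FEATURE_CLASSES <- c("3UTR", "5UTR", "ncRNA", "intron")

#' Read gene-feature and repeat-element interval files
#'
#' Both files are BED6-like, 0-based half-open on disk. The gene file's name
#' field is `gene_id|feature_class` with feature class one of `intron`,
#' `5UTR`, `3UTR`, `ncRNA`; the repeat file's 4th/5th columns are repeat name
#' and repeat family (family `Alu` marks Alu elements). Coordinates are
#' converted to 1-based inclusive internally.
#'
#' @param gene_path path to the gene-feature BED file.
#' @param repeat_path path to the repeat-element BED file.
#' @return A `feature_intervals` object: a list with data frames `genes`
#'   (chrom, start, end, gene_id, feature_class, strand) and `repeats`
#'   (chrom, start, end, repeat_name, repeat_family, strand).
#' @export
read_feature_intervals <- function(gene_path, repeat_path) {
  g <- read_bed6(gene_path, "gene features")
  if (nrow(g)) {
    nm <- strsplit(g$name, "|", fixed = TRUE)
    if (any(lengths(nm) != 2)) fail("read_feature_intervals: gene name field must be 'gene_id|feature_class'")
    nm <- matrix(unlist(nm), ncol = 2, byrow = TRUE)
    bad <- which(!nm[, 2] %in% FEATURE_CLASSES)
    if (length(bad)) fail("read_feature_intervals: unknown feature class '", nm[bad[1], 2], "'")
    genes <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                        gene_id = nm[, 1], feature_class = nm[, 2],
                        strand = g$strand, stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(chrom = character(), start = integer(), end = integer(),
                        gene_id = character(), feature_class = character(),
                        strand = character())
  }
  r <- read_bed6(repeat_path, "repeats")
  repeats <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                        repeat_name = r$name, repeat_family = r$extra,
                        strand = r$strand, stringsAsFactors = FALSE)
  structure(list(genes = genes, repeats = repeats), class = "feature_intervals")
}

#' Write gene-feature and repeat intervals as BED6-like files
#'
#' @param features a `feature_intervals` object.
#' @param gene_path,repeat_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_feature_intervals <- function(features, gene_path, repeat_path) {
  g <- features$genes
  writeLines(c("#chrom\tstart\tend\tname\tscore\tstrand",
               if (nrow(g)) paste(g$chrom, g$start - 1L, g$end,
                                  paste0(g$gene_id, "|", g$feature_class),
                                  ".", g$strand, sep = "\t")),
             gene_path)
  r <- features$repeats
  writeLines(c("#chrom\tstart\tend\tname\tfamily\tstrand",
               if (nrow(r)) paste(r$chrom, r$start - 1L, r$end, r$repeat_name,
                                  r$repeat_family, r$strand, sep = "\t")),
             repeat_path)
  invisible(c(gene_path, repeat_path))
}

#' Read a gene-by-sample count matrix
#'
#' TSV with a header line; first column `gene_id`, remaining columns sample
#' ids. Counts must be non-negative. If `cohort_map` is given (named vector
#' sample -> cohort label), every mapped sample must be a column.
#'
#' @param path path to the TSV.
#' @param cohort_map optional named character vector mapping sample ids to
#'   cohort labels.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_count_matrix <- function(path, cohort_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) fail("read_count_matrix: need a gene column plus sample columns")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  if (anyNA(mat)) fail("read_count_matrix: non-numeric entries")
  if (any(mat < 0)) fail("read_count_matrix: negative counts")
  if (!is.null(cohort_map)) {
    missing <- setdiff(names(cohort_map), colnames(mat))
    if (length(missing)) {
      fail("read_count_matrix: samples in cohort map absent from matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  mat
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell marker table
#'
#' CSV with columns `gene`, `cluster`, `pct1`, `pct2`: the fraction of cells
#' expressing the gene inside the cluster (pct1) versus in all other clusters
#' (pct2). Fractions must lie in \[0, 1\].
#'
#' @param path path to the CSV.
#' @return Data frame with columns gene, cluster, pct1, pct2.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("gene", "cluster", "pct1", "pct2")
  if (!all(required %in% names(df))) {
    fail("read_marker_table: need columns ", paste(required, collapse = ", "))
  }
  df <- df[, required]
  if (any(df$pct1 < 0 | df$pct1 > 1 | df$pct2 < 0 | df$pct2 > 1)) {
    fail("read_marker_table: pct values must lie in [0, 1]")
  }
  df
}

#' Write a marker table as CSV
#' @param markers data frame with columns gene, cluster, pct1, pct2.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.csv(markers[, c("gene", "cluster", "pct1", "pct2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table as TSV with stable column order
#' @param records a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
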