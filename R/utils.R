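#' @keywords internal
"_PACKAGE"

# internal: canonical site key string, unique per (chrom, pos, strand, edit_type)
site_key <- function(df) {
  paste(df$chrom, df$pos, df$strand, df$edit_type, sep = "|")
}

# internal: deterministic ordering by (chrom, pos, strand) -- the tie-break
# ordering used everywhere ranked output must be reproducible
site_order <- function(df) {
  order(df$chrom, df$pos, df$strand, df$edit_type, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fail <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
}

# internal: standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
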