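#' Annotate editing sites with gene features and Alu membership
#'
#' Classifies each site by point-in-interval overlap against the gene
#' feature intervals and the repeat intervals. When a site falls in several
#' gene features, precedence is 3'UTR > 5'UTR > ncRNA > intron; within one
#' class the gene whose interval start is nearest to the site wins. A site
#' covered by no gene feature is intergenic (gene_id NA). `in_alu` is TRUE
#' iff the position lies inside any repeat of family `Alu`. Interval
#' membership ignores strand by default; set `strict_strand = TRUE` to
#' require matching strands for gene features.
#'
#' @param sites data frame with columns chrom, pos, strand (and typically
#'   edit_type); e.g. a [site_index()] table or an [edit_table()].
#' @param features a [read_feature_intervals()] object.
#' @param strict_strand require gene feature strand to match site strand.
#' @return `sites` with added columns feature_class (intron/5UTR/3UTR/
#'   ncRNA/intergenic), gene_id (NA for intergenic), in_alu, repeat_name.
#' @export
annotate_sites <- function(sites, features, strict_strand = FALSE) {
  out <- as.data.frame(sites)
  n <- nrow(out)
  out$feature_class <- rep("intergenic", n)
  out$gene_id <- rep(NA_character_, n)
  out$in_alu <- rep(FALSE, n)
  out$repeat_name <- rep(NA_character_, n)
  if (!n) return(out)

  pts <- GenomicRanges::GRanges(out$chrom,
                                IRanges::IRanges(out$pos, width = 1))
  g <- features$genes
  if (nrow(g)) {
    gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
    hits <- GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (strict_strand) {
      ok <- out$strand[qh] == g$strand[sh]
      qh <- qh[ok]; sh <- sh[ok]
    }
    if (length(qh)) {
      # precedence rank, then distance from interval start, then gene id
      prec <- match(g$feature_class[sh], c("3UTR", "5UTR", "ncRNA", "intron"))
      dist <- abs(out$pos[qh] - g$start[sh])
      o <- order(qh, prec, dist, g$gene_id[sh], method = "radix")
      first <- !duplicated(qh[o])
      pick_q <- qh[o][first]; pick_s <- sh[o][first]
      out$feature_class[pick_q] <- g$feature_class[pick_s]
      out$gene_id[pick_q] <- g$gene_id[pick_s]
    }
  }
  r <- features$repeats
  if (nrow(r)) {
    rr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
    hits <- GenomicRanges::findOverlaps(pts, rr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    alu <- r$repeat_family[sh] == "Alu"
    qh <- qh[alu]; sh <- sh[alu]
    if (length(qh)) {
      o <- order(qh, r$start[sh], method = "radix")
      first <- !duplicated(qh[o])
      pick_q <- qh[o][first]; pick_s <- sh[o][first]
      out$in_alu[pick_q] <- TRUE
      out$repeat_name[pick_q] <- r$repeat_name[pick_s]
    }
  }
  out
}

#' Feature-class and Alu composition of an annotated site set
#'
#' @param annotations output of [annotate_sites()]; must be nonempty.
#' @return List with `feature` (named fractions over feature classes,
#'   summing to 1), `alu` (named fractions Alu / non_Alu), and
#'   `genic_fraction` (fraction of sites assigned to any gene).
#' @export
composition_summary <- function(annotations) {
  n <- nrow(annotations)
  if (!n) fail("composition_summary: empty annotation set")
  feat <- table(factor(annotations$feature_class,
                       levels = c(FEATURE_CLASSES, "intergenic")))
  feature <- as.numeric(feat) / n
  names(feature) <- names(feat)
  alu <- c(Alu = sum(annotations$in_alu), non_Alu = sum(!annotations$in_alu))
  list(feature = feature,
       alu = alu / n,
       genic_fraction = sum(!is.na(annotations$gene_id)) / n)
}

SP6_PROMOTER <- "ATTTAGGTGACACTATAG"

#' Design an edited Alu DNA template
#'
#' Builds the in-silico edited counterpart of an Alu element: every listed
#' position (1-based, within the element) must carry an A in the unedited
#' sequence and is replaced by G, mimicking A-to-I editing; all other bases
#' are unchanged. A promoter (default SP6) is prepended to both sequences
#' for synthesis/transcription export.
#'
#' @param unedited DNA string (A/C/G/T).
#' @param edited_positions integer vector of 1-based positions to edit; may
#'   be empty.
#' @param promoter promoter sequence prepended to the exported constructs.
#' @param name template name.
#' @return An `alu_template` list: name, unedited_sequence, edited_sequence
#'   (both without promoter), edited_positions, promoter, and the
#'   promoter-prefixed `unedited_construct` / `edited_construct`.
#' @export
design_edited_template <- function(unedited, edited_positions = integer(),
                                   promoter = SP6_PROMOTER, name = "template") {
  if (!grepl("^[ACGT]*$", unedited)) fail("design_edited_template: sequence must be A/C/G/T")
  bases <- strsplit(unedited, "", fixed = TRUE)[[1]]
  pos <- sort(unique(as.integer(edited_positions)))
  if (length(pos)) {
    bad <- pos[pos < 1 | pos > length(bases)]
    if (length(bad)) fail("design_edited_template: position ", bad[1], " out of range")
    not_a <- pos[bases[pos] != "A"]
    if (length(not_a)) {
      fail("design_edited_template: position ", not_a[1], " holds ",
           bases[not_a[1]], ", not A")
    }
    bases[pos] <- "G"
  }
  edited <- paste(bases, collapse = "")
  structure(list(name = name,
                 unedited_sequence = unedited,
                 edited_sequence = edited,
                 edited_positions = pos,
                 promoter = promoter,
                 unedited_construct = paste0(promoter, unedited),
                 edited_construct = paste0(promoter, edited)),
            class = "alu_template")
}

#' Export an Alu template pair as FASTA
#'
#' Writes the promoter-prefixed unedited and edited constructs.
#'
#' @param template an [design_edited_template()] result.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(template, path) {
  writeLines(c(paste0(">", template$name, "_unedited"),
               template$unedited_construct,
               paste0(">", template$name, "_edited"),
               template$edited_construct),
             path)
  invisible(path)
}
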