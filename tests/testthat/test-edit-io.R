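test_that("edit-site rows parse per the caller dialect", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend\ttype\tstrand\tedits:reads",
               "chr1\t999\t1000\tAG\t+\t3:20"), p)
  tab <- read_edit_table(p, "s1", "NCI")
  expect_s3_class(tab, "edit_table")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$chrom, "chr1")
  expect_equal(tab$pos, 1000L)
  expect_equal(tab$strand, "+")
  expect_equal(tab$edit_type, "AG")
  expect_equal(tab$edits, 3L)
  expect_equal(tab$reads, 20L)
  expect_equal(tab$ratio, 0.15)
  expect_equal(attr(tab, "sample_id"), "s1")
  expect_equal(attr(tab, "cohort"), "NCI")
})

test_that("a header-only file yields an empty table", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#chrom\tstart\tend\ttype\tstrand\tedits:reads", p)
  tab <- read_edit_table(p, "s1", "NCI")
  expect_equal(nrow(tab), 0)
})

test_that("malformed rows are rejected with the offending line number", {
  cases <- list(
    list(row = "chr1\t999\t1000\tAG\t+\t25:20", msg = "invalid counts"),
    list(row = "chr1\t999\t1000\tAG\t+", msg = "6 tab-separated fields"),
    list(row = "chr1\t999\t1000\tAG\t+\t3_20", msg = "edits:reads"),
    list(row = "chr1\t999\t1000\tAX\t+\t3:20", msg = "edit type"),
    list(row = "chr1\t999\t1000\tAG\t*\t3:20", msg = "strand"),
    list(row = "chr1\t999\t1001\tAG\t+\t3:20", msg = "single-base"),
    list(row = "chr1\tx\t1000\tAG\t+\t3:20", msg = "non-integer"))
  for (cs in cases) {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("#h", cs$row), p)
    expect_error(read_edit_table(p, "s", "c"), cs$msg)
    expect_error(read_edit_table(p, "s", "c"), "line 2")
  }
})

test_that("duplicate site keys within one sample are rejected", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t999\t1000\tAG\t+\t3:20", "chr1\t999\t1000\tAG\t+\t4:21"), p)
  expect_error(read_edit_table(p, "s1", "NCI"), "duplicate")
})

test_that("edit tables round-trip through the dialect exactly", {
  set.seed(41)
  for (i in 1:5) {
    pool <- random_site_pool(25)
    reads <- sample(6:80, 25, replace = TRUE)
    edits <- pmax(1, rbinom(25, reads, 0.3))
    tab <- make_table(pool$chrom, pool$pos, pool$strand, pool$edit_type,
                      edits, reads)
    p <- withr::local_tempfile(fileext = ".tsv")
    write_edit_table(tab, p)
    back <- read_edit_table(p, "s1", "NCI")
    expect_equal(as.data.frame(back), as.data.frame(tab))
  }
})

test_that("BED half-open repeat intervals become 1-based inclusive", {
  gp <- withr::local_tempfile(fileext = ".bed")
  rp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tG1|intron\t.\t+", gp)
  writeLines("chr1\t500\t800\tAluSg4\tAlu\t+", rp)
  f <- read_feature_intervals(gp, rp)
  expect_equal(f$repeats$start, 501L)
  expect_equal(f$repeats$end, 800L)
  expect_equal(f$genes$start, 101L)
  expect_equal(f$genes$end, 200L)
  expect_equal(f$genes$gene_id, "G1")
  expect_equal(f$genes$feature_class, "intron")
  # boundary point queries under the conversion
  ann <- annotate_sites(data.frame(chrom = "chr1", pos = c(500L, 501L, 800L, 801L),
                                   strand = "+"), f)
  expect_equal(ann$in_alu, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("interval files validate coordinates and feature classes", {
  gp <- withr::local_tempfile(fileext = ".bed")
  rp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tG1|intron\t.\t+", gp)
  writeLines(character(), rp)
  expect_error(read_feature_intervals(gp, rp), "start >= end")
  writeLines("chr1\t100\t200\tG1|exon\t.\t+", gp)
  expect_error(read_feature_intervals(gp, rp), "unknown feature class")
  # empty repeat file: valid store, every Alu query negative
  writeLines("chr1\t100\t200\tG1|intron\t.\t+", gp)
  f <- read_feature_intervals(gp, rp)
  ann <- annotate_sites(data.frame(chrom = "chr1", pos = 150L, strand = "+"), f)
  expect_false(ann$in_alu)
})

test_that("count matrices round-trip and reject invalid input", {
  m <- matrix(c(5, 0, 12, 7), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, p)
  expect_equal(read_count_matrix(p), m)
  m2 <- m; m2[1, 1] <- -1
  write_count_matrix(m2, p)
  expect_error(read_count_matrix(p), "negative")
  write_count_matrix(m, p)
  expect_error(read_count_matrix(p, cohort_map = c(s1 = "control", s9 = "case")),
               "absent from matrix")
})

test_that("marker tables round-trip and validate pct bounds", {
  mk <- data.frame(gene = c("PDGFRB", "GFAP"), cluster = c("pericyte", "astrocyte"),
                   pct1 = c(0.62, 0.8), pct2 = c(0.03, 0.05))
  p <- withr::local_tempfile(fileext = ".csv")
  write_marker_table(mk, p)
  back <- read_marker_table(p)
  expect_equal(back, mk)
  mk$pct1[1] <- 1.2
  write_marker_table(mk, p)
  expect_error(read_marker_table(p), "\\[0, 1\\]")
})

test_that("real-valued result tables round-trip to within 1e-9", {
  df <- data.frame(gene = c("a", "b"), value = c(1 / 3, exp(1)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_results(df, p)
  back <- utils::read.delim(p)
  expect_equal(back$value, df$value, tolerance = 1e-9)
})
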