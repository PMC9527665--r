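pres_from <- function(...) build_presence(list(...))

test_that("per-site index is mean ratio times number of edited samples", {
  s1 <- make_table(c("chr1", "chr1"), c(10, 20), "+", "AG", c(4, 6), c(20, 20),
                   sample_id = "s1")
  s2 <- make_table("chr1", 10, "+", "AG", 8, 20, sample_id = "s2")
  rec <- site_index(pres_from(s1, s2), filter_config())
  # site at 10: ratios {0.2, 0.4} -> mean 0.3, index 0.6; site at 20 in one
  # sample only -> omitted
  expect_equal(nrow(rec), 1)
  expect_equal(rec$pos, 10)
  expect_equal(rec$n_samples, 2L)
  expect_equal(rec$mean_ratio, 0.3)
  expect_equal(rec$index, 0.6)
})

test_that("every emitted index exceeds the analytic floor", {
  cfg <- filter_config()
  expect_equal(site_index_floor(cfg), 0.1)
  expect_equal(site_index_floor(filter_config(min_ratio_exclusive = 0.1,
                                              min_samples_inclusive = 3)), 0.3)
  set.seed(31)
  for (i in 1:5) {
    pool <- random_site_pool(50)
    tables <- lapply(random_cohort(pool, 5), filter_sites, cfg)
    rec <- site_index(build_presence(tables), cfg)
    if (nrow(rec)) {
      expect_gt(min(rec$index), site_index_floor(cfg))
      expect_lte(max(rec$index), 5)  # bounded by cohort size
    }
  }
})

test_that("genome-wide index is the order-independent sum of site indices", {
  s1 <- make_table(c("chr1", "chr2"), c(10, 10), "+", "AG", c(4, 12), c(20, 20),
                   sample_id = "s1")
  s2 <- make_table(c("chr1", "chr2"), c(10, 10), "+", "AG", c(8, 12), c(20, 20),
                   sample_id = "s2")
  gw <- genome_wide_index(site_index(pres_from(s1, s2), filter_config()))
  expect_equal(gw$total, 0.6 + 1.2)
  expect_equal(gw$ranked$index, c(1.2, 0.6))
  expect_equal(gw$ranked$rank, 1:2)
  # empty cohort: zero total, empty ranking
  empty <- site_index(pres_from(make_table("chr1", 1, "+", "AG", 5, 20)),
                      filter_config())
  expect_equal(genome_wide_index(empty)$total, 0)
  # random instance against re-summation in reversed order
  set.seed(13)
  pool <- random_site_pool(40)
  rec <- site_index(build_presence(random_cohort(pool, 4)), filter_config())
  expect_equal(genome_wide_index(rec)$total, sum(rev(rec$index)),
               tolerance = 1e-12)
})

test_that("duplicating every sample doubles each per-site index", {
  set.seed(17)
  pool <- random_site_pool(30)
  tables <- random_cohort(pool, 3)
  doubled <- c(tables, lapply(tables, function(t) {
    edit_table(as.data.frame(t), paste0(attr(t, "sample_id"), "_dup"),
               attr(t, "cohort"))
  }))
  r1 <- site_index(build_presence(tables), filter_config())
  r2 <- site_index(build_presence(doubled), filter_config())
  shared <- intersect(paste(r1$chrom, r1$pos), paste(r2$chrom, r2$pos))
  i1 <- r1$index[match(shared, paste(r1$chrom, r1$pos))]
  i2 <- r2$index[match(shared, paste(r2$chrom, r2$pos))]
  expect_equal(i2, 2 * i1)
})

site_recs <- function(pos, index, gene, chrom = "chr1") {
  n <- length(pos)
  recs <- data.frame(cohort = rep("X", n), chrom = rep(chrom, n), pos = pos,
                     strand = rep("+", n), edit_type = rep("AG", n),
                     n_samples = rep(2L, n), mean_ratio = index / 2,
                     index = index, stringsAsFactors = FALSE)
  ann <- data.frame(chrom = rep(chrom, n), pos = pos, strand = rep("+", n),
                    edit_type = rep("AG", n),
                    feature_class = ifelse(is.na(gene), "intergenic", "intron"),
                    gene_id = gene, in_alu = rep(TRUE, n),
                    repeat_name = rep("AluY", n), stringsAsFactors = FALSE)
  list(recs = recs, ann = ann)
}

test_that("per-gene indices sum site indices and genes plus intergenic partition the total", {
  x <- site_recs(1:8 * 10, c(0.6, 1.2, 0.3, 0.2, 0.2, 0.2, 0.5, 0.4),
                 c(rep("G1", 6), "G2", NA))
  g <- gene_site_index(x$recs, x$ann)
  expect_equal(g$genes$index[g$genes$gene_id == "G1"], 2.7)
  expect_equal(g$genes$n_sites[g$genes$gene_id == "G1"], 6L)
  expect_equal(g$intergenic_index, 0.4)
  expect_equal(sum(g$genes$index) + g$intergenic_index,
               genome_wide_index(x$recs)$total, tolerance = 1e-9)
})

test_that("case/control gene comparison applies the >5-site rule and sentinels", {
  # G1: 6 case sites summing 2.7, control 6 sites summing 5.4 -> log2 = -1
  case <- site_recs(1:6 * 10, c(0.6, 1.2, 0.3, 0.2, 0.2, 0.2), rep("G1", 6))
  ctrl <- site_recs(1:6 * 10, rep(0.9, 6), rep("G1", 6))
  out <- per_gene_index(case$recs, ctrl$recs, case$ann)
  expect_equal(out$log2_ratio, -1)
  expect_equal(out$category, "both")
  # exactly 5 sites in both cohorts: excluded (strict > 5)
  case5 <- site_recs(1:5 * 10, rep(0.5, 5), rep("G1", 5))
  ctrl5 <- site_recs(1:5 * 10, rep(0.5, 5), rep("G1", 5))
  expect_equal(nrow(per_gene_index(case5$recs, ctrl5$recs, case5$ann)), 0)
  # control cohort without the gene: sentinel case_only, index carried
  empty <- site_recs(integer(), numeric(), character())
  only <- per_gene_index(case$recs, empty$recs, case$ann)
  expect_equal(only$category, "case_only")
  expect_true(is.na(only$log2_ratio))
  expect_equal(only$index_case, 2.7)
  only2 <- per_gene_index(empty$recs, case$recs, case$ann)
  expect_equal(only2$category, "control_only")
})
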