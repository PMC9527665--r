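test_that("sites annotate by point overlap with feature precedence", {
  f <- toy_features()
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                      pos = c(250L, 550L, 460L, 350L, 100L),
                      strand = c("+", "+", "-", "+", "+"))
  ann <- annotate_sites(sites, f)
  # inside GA's intron AND the AluSg4 repeat; 5UTR beats intron at 250
  expect_equal(ann$feature_class[1], "5UTR")
  expect_equal(ann$gene_id[1], "GA")
  expect_true(ann$in_alu[1])
  expect_equal(ann$repeat_name[1], "AluSg4")
  # 550 overlaps GA 3UTR, GA intron and GB 3UTR: 3UTR wins; GB's interval
  # start (451) is nearer than GA's (501)? no: |550-501| = 49 < |550-451| = 99
  expect_equal(ann$feature_class[2], "3UTR")
  expect_equal(ann$gene_id[2], "GA")
  # 460 overlaps GA intron and GB 3UTR (overlapping genes): 3UTR precedence
  expect_equal(ann$feature_class[3], "3UTR")
  expect_equal(ann$gene_id[3], "GB")
  # chr2 350: ncRNA gene, non-Alu repeat -> not in Alu
  expect_equal(ann$feature_class[4], "ncRNA")
  expect_false(ann$in_alu[4])
  # covered by nothing -> intergenic, no gene
  expect_equal(ann$feature_class[5], "intergenic")
  expect_true(is.na(ann$gene_id[5]))
  expect_false(ann$in_alu[5])
})

test_that("strict strand mode drops discordant gene assignments", {
  f <- toy_features()
  site <- data.frame(chrom = "chr1", pos = 250L, strand = "-")
  expect_equal(annotate_sites(site, f)$gene_id, "GA")
  expect_true(is.na(annotate_sites(site, f, strict_strand = TRUE)$gene_id))
})

test_that("composition fractions partition the site set", {
  ann <- data.frame(feature_class = c(rep("intron", 5), rep("3UTR", 3),
                                      "5UTR", "intergenic"),
                    gene_id = c(rep("G", 9), NA),
                    in_alu = c(rep(TRUE, 9), FALSE))
  comp <- composition_summary(ann)
  expect_equal(sum(comp$feature), 1, tolerance = 1e-12)
  expect_equal(sum(comp$alu), 1, tolerance = 1e-12)
  expect_equal(unname(comp$alu["Alu"]), 0.9)
  expect_equal(comp$genic_fraction, 0.9)
  expect_equal(unname(comp$feature["intron"]), 0.5)
  expect_error(composition_summary(ann[0, ]), "empty")
  all_inter <- data.frame(feature_class = "intergenic", gene_id = NA,
                          in_alu = FALSE)
  expect_equal(composition_summary(all_inter)$genic_fraction, 0)
})

test_that("annotation recovers the generator's Alu placement fraction", {
  cfg <- sim_config(seed = 3, n_genes = 150, n_lineages = 0,
                    markers_per_lineage = 0, alu_fraction = 0.95)
  truth <- simulate_truth(cfg)
  ann <- annotate_sites(truth$sites, truth$features)
  expect_equal(ann$in_alu, truth$sites$in_alu)
  expect_equal(ann$gene_id, truth$sites$gene_id)
  expect_equal(ann$feature_class, truth$sites$feature_class)
  n <- nrow(ann)
  frac <- composition_summary(ann)$alu[["Alu"]]
  expect_lt(abs(frac - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})

test_that("edited templates substitute A to G at the declared positions only", {
  t <- design_edited_template("GGAATT", c(3), promoter = "ATTTAGGTGACACTATAG")
  expect_equal(t$edited_sequence, "GGGATT")
  expect_equal(t$unedited_sequence, "GGAATT")
  expect_equal(t$edited_construct, paste0("ATTTAGGTGACACTATAG", "GGGATT"))
  expect_equal(t$unedited_construct, paste0("ATTTAGGTGACACTATAG", "GGAATT"))
  # empty edit set: identity
  t0 <- design_edited_template("GGAATT", integer())
  expect_equal(t0$edited_sequence, t0$unedited_sequence)
  # non-A position and out-of-range position are named in the error
  expect_error(design_edited_template("GGAATT", 5), "position 5 holds T")
  expect_error(design_edited_template("GGAATT", 7), "position 7 out of range")
  expect_error(design_edited_template("GGANTT", 3), "A/C/G/T")
})

test_that("template editing is exhaustive and idempotent on random sequences", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    seqv <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    a_pos <- which(seqv == "A")
    if (length(a_pos) < 2) next
    pick <- sort(a_pos[sample.int(length(a_pos),
                                  sample(1:min(8, length(a_pos)), 1))])
    t <- design_edited_template(paste(seqv, collapse = ""), pick)
    edited <- strsplit(t$edited_sequence, "")[[1]]
    expect_equal(which(edited != seqv), pick)
    expect_true(all(edited[pick] == "G"))
    # re-apply on the non-edited A's: the already-edited output is unchanged
    # at previously edited positions (idempotence of the substitution)
    rest <- setdiff(a_pos, pick)
    t2 <- design_edited_template(t$edited_sequence, rest)
    expect_equal(strsplit(t2$edited_sequence, "")[[1]][pick], rep("G", length(pick)))
    expect_error(design_edited_template(t$edited_sequence, pick),
                 "holds G")
  }
})

test_that("template FASTA export carries the promoter-prefixed pair", {
  t <- design_edited_template("GGAATT", 3, name = "MDM4_AluSg4")
  p <- withr::local_tempfile(fileext = ".fa")
  write_template_fasta(t, p)
  lines <- readLines(p)
  expect_equal(lines[1], ">MDM4_AluSg4_unedited")
  expect_equal(lines[2], t$unedited_construct)
  expect_equal(lines[4], t$edited_construct)
})
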