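LINEAGE_NAMES <- c("astrocyte", "BEC_arterial", "BEC_capillary", "BEC_venous",
                   "ependymal", "microglia_macrophage", "meningeal_fibroblast",
                   "neuron", "oligodendrocyte", "OPC", "pericyte",
                   "perivascular_fibroblast", "smooth_muscle", "T_cell")

#' Configuration for the synthetic-data generator
#'
#' Defines the simulated study: two cohorts of brain-vasculature-style bulk
#' RNA-seq samples whose per-site A-to-I edit probabilities differ by a
#' multiplicative `retention` factor in the case cohort (retention 1 = no
#' loss; the default 0.5 encodes a uniform 50% loss of editing). Sites are
#' placed in gene features with Alu-biased placement, read depths are
#' negative binomial, per-site baseline edit ratios are Beta-distributed,
#' and 14 cell lineages each contribute a block of marker genes with
#' pct1/pct2 detection structure. All randomness is fixed by `seed`.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_control,n_case cohort sizes (default 7 + 7).
#' @param n_genes number of simulated genes (default 760: 14 lineages x 50
#'   markers + background genes).
#' @param sites_per_gene_mean,sites_per_gene_dispersion negative binomial
#'   parameters for editing sites per gene (default mean 10).
#' @param alu_fraction probability a site lies inside an Alu element
#'   (default 0.95).
#' @param depth_mean,depth_size negative binomial read depth at a site
#'   (default mu 100, size 10: deep bulk coverage).
#' @param ratio_shape1,ratio_shape2 Beta parameters of the per-site baseline
#'   (control) edit ratio (default Beta(2, 8), mean 0.2, most mass at the
#'   low ratios typical of Alu sites).
#' @param retention multiplicative factor in (0, 1] applied to case-cohort
#'   edit probabilities (default 0.5).
#' @param lineage_retention optional named vector of per-lineage retention
#'   overrides (models the localized-loss alternative).
#' @param n_lineages,markers_per_lineage lineage-marker structure (default
#'   14 x 50).
#' @param decoys_per_lineage non-marker rows per lineage in the marker table
#'   (pct1/pct2 ratio below the selection threshold).
#' @param ncrna_fraction fraction of genes simulated as single-feature
#'   noncoding RNAs.
#' @param cohort_labels labels for the two cohorts (default NCI / AD).
#' @param expr_mean,expr_size negative binomial parameters for expression
#'   counts (default mu 500, size 20).
#' @param panel_genes_per_panel genes per expression panel (ISG, NFKB).
#' @param panel_fold case-cohort fold change applied to panel genes
#'   (default 2).
#' @param rbp_factor expression factor applied to RNA-binding-protein genes
#'   in the affected case samples (default 0.4).
#' @param rbp_affected number of case samples carrying the RBP knockdown
#'   pattern (default 5 of 7).
#' @param n_background_expr background (no-effect) genes in the expression
#'   matrix (default 2000, so panel effects barely perturb library sizes, as
#'   in a transcriptome-scale matrix).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_control = 7, n_case = 7,
                       n_genes = 760,
                       sites_per_gene_mean = 10, sites_per_gene_dispersion = 5,
                       alu_fraction = 0.95,
                       depth_mean = 100, depth_size = 10,
                       ratio_shape1 = 2, ratio_shape2 = 8,
                       retention = 0.5,
                       lineage_retention = NULL,
                       n_lineages = 14, markers_per_lineage = 50,
                       decoys_per_lineage = 25,
                       ncrna_fraction = 0.05,
                       cohort_labels = c(control = "NCI", case = "AD"),
                       expr_mean = 500, expr_size = 20,
                       panel_genes_per_panel = 25,
                       panel_fold = 2,
                       rbp_factor = 0.4, rbp_affected = 5,
                       n_background_expr = 2000) {
  cfg <- as.list(environment())
  check <- function(ok, field, msg) if (!ok) fail("sim_config: ", field, " ", msg)
  check(is_count(seed), "seed", "must be an integer")
  check(is_count(n_control) && n_control >= 1, "n_control", "must be >= 1")
  check(is_count(n_case) && n_case >= 1, "n_case", "must be >= 1")
  check(is_count(n_genes) && n_genes >= 1, "n_genes", "must be >= 1")
  check(sites_per_gene_mean > 0, "sites_per_gene_mean", "must be > 0")
  check(alu_fraction > 0 && alu_fraction <= 1, "alu_fraction", "must lie in (0, 1]")
  check(depth_mean > 0 && depth_size > 0, "depth_mean/depth_size", "must be > 0")
  check(ratio_shape1 > 0 && ratio_shape2 > 0, "ratio_shape1/ratio_shape2", "must be > 0")
  check(retention > 0 && retention <= 1, "retention", "must lie in (0, 1]")
  if (!is.null(lineage_retention)) {
    check(all(lineage_retention > 0 & lineage_retention <= 1),
          "lineage_retention", "entries must lie in (0, 1]")
  }
  check(is_count(n_lineages) && n_lineages >= 0, "n_lineages", "must be >= 0")
  check(n_lineages <= length(LINEAGE_NAMES), "n_lineages",
        paste("must be <=", length(LINEAGE_NAMES)))
  check(n_lineages * markers_per_lineage <= n_genes, "n_lineages",
        "x markers_per_lineage exceeds n_genes")
  check(rbp_factor > 0, "rbp_factor", "must be > 0")
  structure(cfg, class = "sim_config")
}

# gene layout constants: every simulated gene spans GENE_SPAN bases with
# sites restricted to fixed slots >= SLOT_STEP apart so that the +/-150 b
# Alu windows around Alu-designated sites never cover another site
GENE_SPAN <- 20000L
SLOT_STEP <- 400L

#' Simulate the ground truth behind a two-cohort editing study
#'
#' Lays out genes (with 5'UTR/intron/3'UTR structure or as ncRNAs) on a
#' synthetic genome, places editing sites in them with Alu-biased placement,
#' draws per-site baseline edit ratios, applies the retention factor to the
#' case cohort, and builds the lineage marker table. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List: `features` (a `feature_intervals` object), `sites` (data
#'   frame with chrom, pos, strand, edit_type, gene_id, feature_class,
#'   in_alu, ratio_control, ratio_case), `lineage_map` (named list lineage
#'   -> marker gene ids), `markers` (marker table data frame), `config`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_ids <- sprintf("GENE%04d", seq_len(ng))
  chrom <- paste0("chr", ((seq_len(ng) - 1) %% 22) + 1)
  slot_on_chrom <- (seq_len(ng) - 1) %/% 22
  gstart <- slot_on_chrom * (GENE_SPAN + 5000L) + 1L
  strand <- rep(c("+", "-"), length.out = ng)
  is_ncrna <- stats::runif(ng) < cfg$ncrna_fraction

  # gene feature intervals (1-based inclusive)
  feats <- lapply(seq_len(ng), function(i) {
    s <- gstart[i]
    if (is_ncrna[i]) {
      data.frame(chrom = chrom[i], start = s, end = s + GENE_SPAN - 1L,
                 gene_id = gene_ids[i], feature_class = "ncRNA",
                 strand = strand[i], stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = chrom[i],
                 start = c(s, s + 1000L, s + 15000L),
                 end = c(s + 999L, s + 14999L, s + GENE_SPAN - 1L),
                 gene_id = gene_ids[i],
                 feature_class = c("5UTR", "intron", "3UTR"),
                 strand = strand[i], stringsAsFactors = FALSE)
    }
  })
  genes <- do.call(rbind, feats)

  # sites: pick distinct slots within each gene
  n_slots <- GENE_SPAN %/% SLOT_STEP
  k <- pmin(n_slots,
            1L + stats::rnbinom(ng, mu = cfg$sites_per_gene_mean - 1,
                                size = cfg$sites_per_gene_dispersion))
  site_rows <- lapply(seq_len(ng), function(i) {
    slots <- sort(sample.int(n_slots, k[i]))
    pos <- gstart[i] + (slots - 1L) * SLOT_STEP + 200L
    data.frame(chrom = chrom[i], pos = pos, strand = strand[i],
               gene_id = gene_ids[i], stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_rows)
  ns <- nrow(sites)
  sites$edit_type <- ifelse(sites$strand == "+", "AG", "TC")
  sites$in_alu <- stats::runif(ns) < cfg$alu_fraction
  # feature class by position within the gene body
  off <- sites$pos - gstart[match(sites$gene_id, gene_ids)]
  sites$feature_class <- ifelse(is_ncrna[match(sites$gene_id, gene_ids)], "ncRNA",
                         ifelse(off < 1000L, "5UTR",
                         ifelse(off < 15000L, "intron", "3UTR")))
  sites$ratio_control <- stats::rbeta(ns, cfg$ratio_shape1, cfg$ratio_shape2)

  # lineage map and per-gene retention
  lineages <- LINEAGE_NAMES[seq_len(cfg$n_lineages)]
  lineage_map <- list()
  gene_retention <- rep(cfg$retention, ng)
  names(gene_retention) <- gene_ids
  if (cfg$n_lineages > 0) {
    for (j in seq_along(lineages)) {
      block <- gene_ids[((j - 1) * cfg$markers_per_lineage + 1):(j * cfg$markers_per_lineage)]
      lineage_map[[lineages[j]]] <- block
      if (!is.null(cfg$lineage_retention) && lineages[j] %in% names(cfg$lineage_retention)) {
        gene_retention[block] <- cfg$lineage_retention[[lineages[j]]]
      }
    }
  }
  sites$ratio_case <- sites$ratio_control * gene_retention[sites$gene_id]

  # repeats: a +/-150 b Alu window around each Alu site; an L1 window around
  # a tenth of the non-Alu sites so the family filter is exercised
  alu_idx <- which(sites$in_alu)
  l1_idx <- which(!sites$in_alu)
  l1_idx <- l1_idx[stats::runif(length(l1_idx)) < 0.1]
  repeats <- rbind(
    if (length(alu_idx)) {
      data.frame(chrom = sites$chrom[alu_idx],
                 start = pmax(1L, sites$pos[alu_idx] - 150L),
                 end = sites$pos[alu_idx] + 149L,
                 repeat_name = sprintf("AluY_%05d", seq_along(alu_idx)),
                 repeat_family = "Alu",
                 strand = sites$strand[alu_idx], stringsAsFactors = FALSE)
    },
    if (length(l1_idx)) {
      data.frame(chrom = sites$chrom[l1_idx],
                 start = pmax(1L, sites$pos[l1_idx] - 150L),
                 end = sites$pos[l1_idx] + 149L,
                 repeat_name = sprintf("L1_%05d", seq_along(l1_idx)),
                 repeat_family = "L1",
                 strand = sites$strand[l1_idx], stringsAsFactors = FALSE)
    })

  markers <- simulate_markers(lineage_map, gene_ids, cfg)
  rownames(sites) <- NULL
  list(features = structure(list(genes = genes, repeats = repeats),
                            class = "feature_intervals"),
       sites = sites,
       lineage_map = lineage_map,
       markers = markers,
       config = cfg)
}

# internal: marker table with true markers (pct1/pct2 ratio in [12, 40],
# occasionally pct2 = 0) and decoy rows (ratio in [1, 8])
simulate_markers <- function(lineage_map, gene_ids, cfg) {
  rows <- lapply(names(lineage_map), function(lin) {
    genes <- lineage_map[[lin]]
    m <- length(genes)
    pct1 <- stats::runif(m, 0.3, 0.9)
    ratio <- stats::runif(m, 12, 40)
    pct2 <- pct1 / ratio
    pct2[stats::runif(m) < 0.05] <- 0
    others <- setdiff(gene_ids, genes)
    nd <- min(cfg$decoys_per_lineage, length(others))
    dgenes <- sample(others, nd)
    dpct1 <- stats::runif(nd, 0.1, 0.6)
    dpct2 <- pmin(1, dpct1 / stats::runif(nd, 1, 8))
    data.frame(gene = c(genes, dgenes), cluster = lin,
               pct1 = c(pct1, dpct1), pct2 = c(pct2, dpct2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), cluster = character(),
                      pct1 = numeric(), pct2 = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Simulate per-sample edit-site tables for both cohorts
#'
#' For every sample and site, total reads are drawn from the depth
#' distribution and edited reads binomially at the site's true cohort
#' ratio. A site appears in a sample's table only when at least one edited
#' read was drawn (callers only report observed edits). Deterministic given
#' `cfg$seed`.
#'
#' @param truth output of [simulate_truth()].
#' @param cfg the same [sim_config()].
#' @return List with elements `control` and `case`, each a named list of
#'   [edit_table()] objects.
#' @export
simulate_cohorts <- function(truth, cfg = truth$config) {
  set.seed(cfg$seed + 1L)
  sites <- truth$sites
  ns <- nrow(sites)
  one_cohort <- function(n_samples, ratios, label, prefix) {
    tables <- lapply(seq_len(n_samples), function(s) {
      reads <- stats::rnbinom(ns, mu = cfg$depth_mean, size = cfg$depth_size)
      edits <- integer(ns)
      pos_reads <- reads > 0
      edits[pos_reads] <- stats::rbinom(sum(pos_reads), reads[pos_reads],
                                        ratios[pos_reads])
      keep <- edits >= 1
      edit_table(data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                            strand = sites$strand[keep],
                            edit_type = sites$edit_type[keep],
                            edits = edits[keep], reads = reads[keep],
                            stringsAsFactors = FALSE),
                 sample_id = sprintf("%s_%d", prefix, s), cohort = label)
    })
    names(tables) <- vapply(tables, attr, "", "sample_id")
    tables
  }
  list(control = one_cohort(cfg$n_control, sites$ratio_control,
                            cfg$cohort_labels[["control"]],
                            cfg$cohort_labels[["control"]]),
       case = one_cohort(cfg$n_case, sites$ratio_case,
                         cfg$cohort_labels[["case"]],
                         cfg$cohort_labels[["case"]]))
}

#' Write simulated cohort tables to disk in the caller dialect
#'
#' @param cohorts output of [simulate_cohorts()].
#' @param dir output directory (created if missing).
#' @return Named list (`control`, `case`) of named file-path vectors.
#' @export
write_cohort_tables <- function(cohorts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lapply(cohorts, function(tables) {
    paths <- vapply(tables, function(t) {
      p <- file.path(dir, paste0(attr(t, "sample_id"), ".tsv"))
      write_edit_table(t, p)
      p
    }, "")
    paths
  })
}

#' Simulate a gene-by-sample expression matrix with panel effects
#'
#' Negative-binomial counts around per-gene lognormal baselines. In case
#' samples, interferon-stimulated (ISG) and NF-kB panel genes are scaled by
#' `cfg$panel_fold`; a set of RNA-binding-protein genes is scaled by
#' `cfg$rbp_factor` in the first `cfg$rbp_affected` case samples only
#' (modelling sample-specific RBP loss). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List: `counts` (matrix), `lengths` (named gene lengths, bases),
#'   `cohorts` (named vector sample -> control/case), `panels` (list of ISG
#'   and NFKB gene ids), `rbp_genes`, `affected_samples` (case samples
#'   carrying the RBP effect), `background_genes`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  panels <- list(ISG = sprintf("ISG_%02d", seq_len(cfg$panel_genes_per_panel)),
                 NFKB = sprintf("NFKB_%02d", seq_len(cfg$panel_genes_per_panel)))
  rbp_genes <- c("ADAR", "ADARB1", "XRCC6", "SBDS", "DDX5", "FXR1")
  bg <- sprintf("BG_%03d", seq_len(cfg$n_background_expr))
  genes <- c(panels$ISG, panels$NFKB, rbp_genes, bg)
  ngene <- length(genes)
  samples <- c(sprintf("%s_%d", cfg$cohort_labels[["control"]], seq_len(cfg$n_control)),
               sprintf("%s_%d", cfg$cohort_labels[["case"]], seq_len(cfg$n_case)))
  cohorts <- stats::setNames(rep(c("control", "case"), c(cfg$n_control, cfg$n_case)),
                             samples)
  affected <- samples[cohorts == "case"][seq_len(min(cfg$rbp_affected, cfg$n_case))]
  baseline <- stats::rlnorm(ngene, meanlog = log(cfg$expr_mean), sdlog = 0.5)
  names(baseline) <- genes
  mu <- matrix(baseline, nrow = ngene, ncol = length(samples),
               dimnames = list(genes, samples))
  mu[c(panels$ISG, panels$NFKB), cohorts == "case"] <-
    mu[c(panels$ISG, panels$NFKB), cohorts == "case"] * cfg$panel_fold
  mu[rbp_genes, affected] <- mu[rbp_genes, affected] * cfg$rbp_factor
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = cfg$expr_size),
                   nrow = ngene, dimnames = dimnames(mu))
  lengths <- stats::setNames(sample(800:4000, ngene, replace = TRUE), genes)
  list(counts = counts, lengths = lengths, cohorts = cohorts,
       panels = panels, rbp_genes = rbp_genes, affected_samples = affected,
       background_genes = bg)
}
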