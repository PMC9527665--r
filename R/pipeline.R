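#' Configuration for a full pipeline run
#'
#' Collects the file inputs and options for [run_full_analysis()]. Only the
#' two cohorts' edit tables and the annotation files are required; marker
#' and expression inputs are optional, and their stages are skipped with a
#' warning when absent.
#'
#' @param control_files,case_files named character vectors of edit-table
#'   paths (names are sample ids).
#' @param control_label,case_label cohort labels.
#' @param gene_features,repeats paths to the BED-like annotation files.
#' @param marker_path optional marker-table CSV.
#' @param counts_path optional count-matrix TSV.
#' @param lengths_path optional gene-length TSV (columns gene_id, length),
#'   enabling FPKM for the panel stage.
#' @param panel_paths optional named list of gene-list files (one symbol per
#'   line), e.g. `list(ISG = ..., NFKB = ...)`.
#' @param rbp_path optional gene-list file of RNA-binding-protein genes for
#'   the per-sample ratio screen.
#' @param filter a [filter_config()].
#' @param out_dir output directory.
#' @param seed seed for permutation p-values.
#' @param use_fpkm use FPKM (requires `lengths_path`) rather than counts in
#'   the expression stages.
#' @return A `run_config` list.
#' @export
run_config <- function(control_files, case_files,
                       control_label = "NCI", case_label = "AD",
                       gene_features, repeats,
                       marker_path = NULL, counts_path = NULL,
                       lengths_path = NULL, panel_paths = NULL,
                       rbp_path = NULL,
                       filter = filter_config(), out_dir, seed = 1,
                       use_fpkm = FALSE) {
  if (is.null(names(control_files)) || is.null(names(case_files))) {
    fail("run_config: cohort file vectors must be named by sample id")
  }
  structure(as.list(environment()), class = "run_config")
}

# internal: run one stage; on error write a FAILED marker and abort with the
# stage name and cause
run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
               file.path(out_dir, paste0("FAILED_", name, ".txt")))
    fail("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full editing-loss analysis
#'
#' Sequences the whole downstream workflow on files: read and filter each
#' sample's edit table, build per-cohort presence, compute common-site sets
#' and the chi-square site-count comparison, per-site and genome-wide
#' editing indices, gene annotation and per-gene case/control log2 ratios,
#' feature/Alu composition, the per-lineage editing comparison (when a
#' marker table is supplied), and the expression screens (when a count
#' matrix is supplied). Each stage writes a numbered TSV under
#' `cfg$out_dir`; a `manifest.json` records the configuration, seed and
#' summary statistics. A stage failure aborts the run, leaving earlier
#' outputs plus a `FAILED_<stage>.txt` marker.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, the output directory.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("aluedit")),
                   filter = unclass(cfg$filter),
                   cohorts = c(control = cfg$control_label, case = cfg$case_label),
                   stages = list())

  # 1: read + filter
  filt <- run_stage("filter", out, {
    read_cohort <- function(files, label) {
      lapply(stats::setNames(names(files), names(files)), function(sid) {
        raw <- read_edit_table(files[[sid]], sid, label)
        list(raw = nrow(raw), table = filter_sites(raw, cfg$filter))
      })
    }
    ctrl <- read_cohort(cfg$control_files, cfg$control_label)
    case <- read_cohort(cfg$case_files, cfg$case_label)
    counts <- do.call(rbind, lapply(c(ctrl, case), function(x) {
      data.frame(sample = attr(x$table, "sample_id"),
                 cohort = attr(x$table, "cohort"),
                 n_sites_raw = x$raw, n_sites_filtered = nrow(x$table))
    }))
    write_results(counts, file.path(out, "01_filtered_site_counts.tsv"))
    list(control = lapply(ctrl, `[[`, "table"),
         case = lapply(case, `[[`, "table"))
  })
  manifest$stages$filter <- "ok"

  # 2: presence + common sites
  pres_ctrl <- build_presence(filt$control)
  pres_case <- build_presence(filt$case)
  report <- run_stage("common_sites", out, {
    rep <- common_sites(pres_ctrl, pres_case)
    write_results(as.data.frame(rep), file.path(out, "02_common_sites.tsv"))
    rep
  })
  cnt <- attr(report, "counts")
  all_ctrl <- cnt[["A_only"]] + cnt[["shared"]]
  all_case <- cnt[["B_only"]] + cnt[["shared"]]
  chi_all <- if (all_ctrl + all_case > 0) compare_site_counts(all_ctrl, all_case)
  manifest$stages$common_sites <- "ok"
  manifest$common_site_counts <- as.list(cnt)
  if (!is.null(chi_all)) {
    manifest$chi2_all_sample_sites <- list(statistic = chi_all$statistic,
                                           p = chi_all$p)
  }

  # 3: site and genome-wide indices per cohort
  idx <- run_stage("site_index", out, {
    si_ctrl <- site_index(pres_ctrl, cfg$filter)
    si_case <- site_index(pres_case, cfg$filter)
    write_results(si_ctrl, file.path(out, paste0("03_site_index_", cfg$control_label, ".tsv")))
    write_results(si_case, file.path(out, paste0("03_site_index_", cfg$case_label, ".tsv")))
    list(control = si_ctrl, case = si_case)
  })
  manifest$stages$site_index <- "ok"
  manifest$genome_wide_index <- list(control = genome_wide_index(idx$control)$total,
                                     case = genome_wide_index(idx$case)$total)
  manifest$qualifying_sites <- list(control = nrow(idx$control),
                                    case = nrow(idx$case))
  if (nrow(idx$control) + nrow(idx$case) > 0) {
    chi_idx <- compare_site_counts(nrow(idx$control), nrow(idx$case))
    manifest$chi2_index_sites <- list(statistic = chi_idx$statistic, p = chi_idx$p)
  }

  # 4-5: annotation, per-gene index, composition
  features <- run_stage("annotation", out, {
    read_feature_intervals(cfg$gene_features, cfg$repeats)
  })
  all_sites <- unique(rbind(idx$control[, c("chrom", "pos", "strand", "edit_type")],
                            idx$case[, c("chrom", "pos", "strand", "edit_type")]))
  ann <- annotate_sites(all_sites, features)
  gene_tab <- run_stage("gene_index", out, {
    g <- per_gene_index(idx$case, idx$control, ann)
    write_results(g, file.path(out, "04_gene_index.tsv"))
    g
  })
  manifest$stages$gene_index <- "ok"
  manifest$n_qualifying_genes <- nrow(gene_tab)
  run_stage("composition", out, {
    comp <- composition_summary(ann)
    df <- rbind(data.frame(partition = "feature", class = names(comp$feature),
                           fraction = unname(comp$feature)),
                data.frame(partition = "alu", class = names(comp$alu),
                           fraction = unname(comp$alu)),
                data.frame(partition = "genic", class = "genic",
                           fraction = comp$genic_fraction))
    write_results(df, file.path(out, "05_annotation_composition.tsv"))
  })
  manifest$stages$composition <- "ok"

  # 6: lineage comparison (optional)
  if (!is.null(cfg$marker_path)) {
    run_stage("lineage", out, {
      markers <- read_marker_table(cfg$marker_path)
      gene_sets <- select_lineage_genes(markers)
      gi_ctrl <- gene_site_index(idx$control, ann)$genes
      gi_case <- gene_site_index(idx$case, ann)$genes
      comp <- lineage_editing_comparison(
        gene_sets,
        stats::setNames(gi_ctrl$index, gi_ctrl$gene_id),
        stats::setNames(gi_case$index, gi_case$gene_id),
        n_control = length(attr(pres_ctrl, "samples")),
        n_case = length(attr(pres_case, "samples")))
      write_results(comp, file.path(out, "06_lineage_comparison.tsv"))
    })
    manifest$stages$lineage <- "ok"
  } else {
    warning("run_full_analysis: no marker table supplied; lineage stage skipped")
    manifest$stages$lineage <- "skipped"
  }

  # 7-8: expression screens (optional)
  if (!is.null(cfg$counts_path)) {
    expr_mat <- run_stage("expression_input", out, {
      mat <- read_count_matrix(cfg$counts_path)
      if (cfg$use_fpkm) {
        if (is.null(cfg$lengths_path)) fail("use_fpkm requires lengths_path")
        len <- utils::read.delim(cfg$lengths_path)
        mat <- fpkm(mat, stats::setNames(len$length, len$gene_id))
      }
      mat
    })
    cohort_map <- stats::setNames(
      rep(c("control", "case"),
          c(length(cfg$control_files), length(cfg$case_files))),
      c(names(cfg$control_files), names(cfg$case_files)))
    cohort_map <- cohort_map[names(cohort_map) %in% colnames(expr_mat)]
    if (!is.null(cfg$rbp_path)) {
      run_stage("ratio_screen", out, {
        genes <- readLines(cfg$rbp_path)
        genes <- genes[nzchar(genes)]
        scr <- ratio_screen(expr_mat, genes, cohort_map)
        write_results(scr, file.path(out, "07_ratio_screen.tsv"))
      })
      manifest$stages$ratio_screen <- "ok"
    } else manifest$stages$ratio_screen <- "skipped"
    if (!is.null(cfg$panel_paths)) {
      run_stage("panel_fold_change", out, {
        panels <- lapply(cfg$panel_paths, function(p) {
          g <- readLines(p); g[nzchar(g)]
        })
        pfc <- panel_fold_change(expr_mat, panels, cohort_map, seed = cfg$seed)
        write_results(pfc, file.path(out, "08_panel_fold_change.tsv"))
        anovas <- lapply(panels, function(g) {
          a <- tryCatch(panel_anova(expr_mat, g, cohort_map),
                        error = function(e) NULL)
          if (is.null(a)) NULL else list(F = a$factor_b$statistic,
                                         p = a$factor_b$p)
        })
        manifest$panel_anova <- anovas
      })
      manifest$stages$panel_fold_change <- "ok"
    } else manifest$stages$panel_fold_change <- "skipped"
  } else {
    warning("run_full_analysis: no count matrix supplied; expression stages skipped")
    manifest$stages$ratio_screen <- "skipped"
    manifest$stages$panel_fold_change <- "skipped"
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
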