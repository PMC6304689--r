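#' Full-run configuration
#'
#' Collects all stage parameters with their published defaults: 500-kb F_ST
#' windows, the hard-filter thresholds, the per-comparison marker rules, the
#' zero-depth / 3x-median copy-state rules, the 0.1 introgression-ancestry
#' threshold, and the 0.25-0.75 ancestral band with 0.2 minimum shift.
#' Unspecified parameters resolve to these defaults; the resolved config is
#' serialized into the output directory.
#'
#' @param out_dir output directory for all stage files.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param sim named list of [sim_config()] overrides (used when no `inputs`
#'   are given).
#' @param inputs optional named list of existing input paths: `vcf`,
#'   `samples`, `genes`, `depth`, `ancestry` (any of the last three may be
#'   omitted; dependent stages are then skipped).
#' @param filter named list of [site_filter_config()] overrides.
#' @param marker named list of [marker_config()] overrides.
#' @param window_bp F_ST window width.
#' @param candidate_window_bp window width for the candidate-gene scan.
#' @param candidate_fst_min,candidate_keyword,candidate_chrom candidate-gene
#'   search parameters.
#' @param top_window_pct,top_gene_pct flagging percentages for windows and
#'   differentiated genes.
#' @param pca_subsample_frac,pca_r2 PCA site subsample fraction and LD
#'   pruning threshold.
#' @param pav_diff_threshold,n_perm permutation-test parameters.
#' @param ancestry_threshold introgression-call threshold.
#' @param focal_sample sample for the absence-enrichment test; `NULL` picks
#'   the highest-coverage sample of the block-carrier pool.
#' @param opv_band,min_shift shift-classifier parameters.
#' @param n_crosses crosses per type in the complementation stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, sim = list(), inputs = NULL,
                       filter = list(), marker = list(),
                       window_bp = 5e5, candidate_window_bp = 1e5,
                       candidate_fst_min = 0.2,
                       candidate_keyword = "pentatricopeptide",
                       candidate_chrom = "chr13",
                       top_window_pct = 5, top_gene_pct = 1,
                       pca_subsample_frac = 0.1, pca_r2 = 0.2,
                       pav_diff_threshold = 0.2, n_perm = 199L,
                       ancestry_threshold = 0.1, focal_sample = NULL,
                       opv_band = c(0.25, 0.75), min_shift = 0.2,
                       n_crosses = 100L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

stage_seed <- function(config, k) (config$seed * 1009L + k) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> filter -> F_ST/PCA -> copy-state/PAV ->
#' introgression enrichment -> shift classification and crosses, writing
#' every stage's tables under `out_dir` together with a manifest and a
#' human-readable summary. A stage failure halts the run with a diagnostic
#' naming the stage. Given the same config and seed the whole bundle is
#' reproducible.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of in-memory stage results plus `manifest` and
#'   `summary_lines`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  res <- list()
  summary_lines <- character()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[length(manifest) + 1]] <<- data.table(
      stage = name, seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    )
    out
  }

  # ---- inputs ------------------------------------------------------------
  ancestry <- NULL; depths <- NULL; genes <- NULL; truth <- NULL
  if (is.null(config$inputs)) {
    sim <- t_stage("simulate", {
      scfg <- do.call(sim_config, modifyList(config$sim,
                                             list(seed = stage_seed(config, 1L)),
                                             keep.null = TRUE))
      gg <- generate_genotypes(scfg)
      gd <- generate_gene_depths(scfg, gg$truth)
      files <- write_outputs(gg$panel, gd$depths, scfg,
                             file.path(config$out_dir, "sim"), gd$truth)
      list(panel = gg$panel, depths = gd$depths, truth = gd$truth,
           scfg = scfg, files = files)
    })
    panel <- sim$panel; depths <- sim$depths; truth <- sim$truth
    genes <- depths$genes
    ancestry <- build_ancestry_track(sim$scfg)
    res$sim_config <- sim$scfg
  } else {
    panel <- t_stage("load", {
      inp <- config$inputs
      if (is.null(inp$vcf) || is.null(inp$samples))
        stop("inputs must include at least 'vcf' and 'samples'")
      read_vcf(inp$vcf, inp$samples)
    })
    inp <- config$inputs
    if (!is.null(inp$genes)) genes <- read_gene_models(inp$genes)
    if (!is.null(inp$depth) && !is.null(genes)) {
      dm <- fread(inp$depth)
      st <- read_sample_table(inp$samples)
      sel <- genes[match(dm$gene_id, gene_id)]
      depths <- gene_depth_matrix(
        sel, st[match(names(dm)[-1], sample_id)],
        as.matrix(dm[, -1])
      )
    }
    if (!is.null(inp$ancestry)) ancestry <- read_ancestry_track(inp$ancestry)
  }

  # ---- filter ------------------------------------------------------------
  filt <- t_stage("filter", {
    fcfg <- do.call(site_filter_config, config$filter)
    apply_site_filters(panel, fcfg)
  })
  fwrite(filt$report, file.path(config$out_dir, "filter_report.tsv"), sep = "\t")
  res$filter_report <- filt$report
  fpanel <- filt$panel
  summary_lines <- c(summary_lines, sprintf(
    "filter: %d / %d sites retained",
    attr(filt$report, "n_passed"), attr(filt$report, "n_input")))

  # ---- F_ST --------------------------------------------------------------
  pairs <- list(c("B", "R"), c("B", "OPV"), c("R", "OPV"))
  pairs <- Filter(function(p) all(p %in% fpanel$samples$group), pairs)
  fst <- t_stage("fst", {
    mcfg <- do.call(marker_config, config$marker)
    lapply(pairs, function(p) {
      comp <- site_fst(fpanel, p[1], p[2], mcfg)
      wins <- top_windows(window_fst(comp, config$window_bp),
                          config$top_window_pct)
      list(pair = p, components = comp, windows = wins,
           genomewide = genomewide_fst(comp))
    })
  })
  for (f in fst) {
    tag <- paste(f$pair, collapse = "_")
    fwrite(f$windows, file.path(config$out_dir,
                                sprintf("fst_windows_%s.tsv", tag)), sep = "\t")
    summary_lines <- c(summary_lines, sprintf(
      "fst %s: genome-wide %.4f over %d markers",
      paste(f$pair, collapse = "-"), f$genomewide, nrow(f$components)))
  }
  res$fst <- fst

  # ---- PCA ---------------------------------------------------------------
  pca <- t_stage("pca", {
    panel_pca(fpanel, n_components = 5L,
              subsample_frac = config$pca_subsample_frac,
              seed = stage_seed(config, 2L), ld_r2 = config$pca_r2)
  })
  fwrite(data.table(sample_id = rownames(pca$scores), pca$scores),
         file.path(config$out_dir, "pca_scores.tsv"), sep = "\t")
  res$pca <- pca

  # ---- candidate genes ---------------------------------------------------
  if (!is.null(genes) && length(fst)) {
    cand <- t_stage("candidate_genes", {
      wins100 <- window_fst(fst[[1]]$components, config$candidate_window_bp)
      candidate_genes(wins100, genes, config$candidate_fst_min,
                      config$candidate_keyword, config$candidate_chrom)
    })
    fwrite(cand, file.path(config$out_dir, "candidate_genes.tsv"), sep = "\t")
    summary_lines <- c(summary_lines,
                       sprintf("candidate genes (%s on %s): %d",
                               config$candidate_keyword,
                               config$candidate_chrom, nrow(cand)))
    res$candidates <- cand
  }

  # ---- PAV ---------------------------------------------------------------
  if (!is.null(depths)) {
    pav <- t_stage("pav", {
      states <- classify_copy_state(depths)
      summ <- pav_summaries(states)
      gp <- top_differentiated(group_pav_freq(states), config$top_gene_pct)
      perm <- permutation_differentiation_test(
        states, diff_threshold = config$pav_diff_threshold,
        n_perm = config$n_perm, seed = stage_seed(config, 3L))
      reg <- depth_absence_regression(data.table(
        median_depth = states$median_depth,
        group = states$samples$group,
        n_absent = summ$per_sample$n_absent))
      lb <- pav_length_bias(states)
      list(states = states, summaries = summ, group_freq = gp,
           perm = perm, regression = reg, length_bias = lb)
    })
    fwrite(pav$summaries$per_sample,
           file.path(config$out_dir, "pav_per_sample.tsv"), sep = "\t")
    fwrite(pav$group_freq, file.path(config$out_dir, "pav_group_freq.tsv"),
           sep = "\t")
    summary_lines <- c(summary_lines, sprintf(
      "pav: %d genes with PAV (%d absent in >1 sample); permutation p (absent) = %.4g",
      length(pav$summaries$sets$absent_any),
      length(pav$summaries$sets$absent_multi), pav$perm$absent$p_value))
    res$pav <- pav

    # ---- introgression ---------------------------------------------------
    if (!is.null(ancestry) && !is.null(genes)) {
      intro <- t_stage("introgression", {
        vals <- gene_introgression_value(ancestry, genes)
        flags <- classify_introgressed(vals, config$ancestry_threshold)
        focal <- config$focal_sample
        if (is.null(focal)) {
          carrier <- pav$states$samples$group == "R"
          cand_s <- which(if (any(carrier)) carrier else
            rep(TRUE, nrow(pav$states$samples)))
          focal <- pav$states$samples$sample_id[
            cand_s[which.max(pav$states$median_depth[cand_s])]]
        }
        idx <- match(genes$gene_id, pav$states$genes$gene_id)
        enr <- absence_enrichment(
          pav$states$state[idx, focal] == "absent", flags)
        list(values = vals, flags = flags, focal = focal, enrichment = enr)
      })
      summary_lines <- c(summary_lines, sprintf(
        "introgression enrichment (%s): %.2f%% absent inside vs %.2f%% outside, chi2 = %.3f, p = %.4g",
        intro$focal, 100 * intro$enrichment$prop_absent_in,
        100 * intro$enrichment$prop_absent_out,
        intro$enrichment$chi2, intro$enrichment$p_value))
      res$introgression <- intro
    } else {
      summary_lines <- c(summary_lines,
                         "introgression: skipped (no ancestry track or gene models)")
    }
  } else {
    summary_lines <- c(summary_lines, "pav: skipped (no depth matrix)")
  }

  # ---- heterosis ---------------------------------------------------------
  if (all(c("OPV", "B", "R") %in% fpanel$samples$group)) {
    het <- t_stage("heterosis", {
      fr <- data.table(
        chrom = fpanel$sites$chrom, pos = fpanel$sites$pos,
        f_opv = group_allele_freq(fpanel, "OPV")$freq,
        f_b = group_allele_freq(fpanel, "B")$freq,
        f_r = group_allele_freq(fpanel, "R")$freq
      )
      cls <- classify_shift(fr, config$opv_band, config$min_shift)
      list(classification = cls, fraction = parallel_fraction(cls),
           windows = windowed_opposite_rate(cls, config$window_bp))
    })
    fwrite(het$classification,
           file.path(config$out_dir, "shift_classification.tsv"), sep = "\t")
    pf <- het$fraction
    summary_lines <- c(summary_lines, sprintf(
      "shift sorting: %d parallel, %d opposite (%.4f parallel)",
      pf$n_parallel, pf$n_opposite,
      ifelse(is.na(pf$fraction_parallel), NaN, pf$fraction_parallel)))
    res$heterosis <- het
  }

  if (!is.null(depths)) {
    crosses <- t_stage("crosses", {
      simulate_crosses(res$pav$states, n_per_type = config$n_crosses,
                       seed = stage_seed(config, 4L))
    })
    fwrite(crosses$summary, file.path(config$out_dir, "cross_summary.tsv"),
           sep = "\t")
    summary_lines <- c(summary_lines, paste(
      "crosses (mean shared-absent):",
      paste(sprintf("%s=%.1f", crosses$summary$type, crosses$summary$mean),
            collapse = ", ")))
    res$crosses <- crosses
  }

  # ---- report ------------------------------------------------------------
  manifest_dt <- rbindlist(manifest)
  fwrite(manifest_dt, file.path(config$out_dir, "manifest.tsv"), sep = "\t")
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  writeLines(deparse(config[setdiff(names(config), "inputs")]),
             file.path(config$out_dir, "config.txt"))
  res$manifest <- manifest_dt
  res$summary_lines <- summary_lines
  invisible(res)
}
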