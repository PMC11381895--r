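#' Default pipeline configuration
#'
#' One hierarchical configuration with per-stage sections; every value can
#' be overridden via a YAML file ([read_pipeline_config()]) or by editing
#' the returned list. All randomness flows from the single `seed`.
#'
#' @param seed root integer seed.
#' @return nested configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulate = list(
      n_cells = 12000, outlier_fraction = 0.05,
      image_size_px = c(2000, 2000), mix_weights = c(0.3, 0.3, 0.4),
      n_regions = 3,
      n_proteins = 1000, base_log2_mean = 22, base_log2_sd = 2.5,
      noise_sd = 0.5, n_markers = 20, marker_log2_fc = 2,
      missing_slope = -0.8, missing_midpoint = 17, missing_floor = 0,
      missing_ceiling = 0.6),
    classify = list(
      outlier_fraction = 0.05, stain_high = 0.25, stain_low = 0.05,
      stromal_area_max_um2 = 40, stromal_ecc_min = 0.75, um_per_px = 0.5,
      lower_pct = 1, upper_pct = 99),
    spatial = list(offset_um = 2, per_class = 1000, replicates = 3,
                   allow_fewer = FALSE, contour_vertices = 16),
    stats = list(q = 0.05, s0 = 0.1, min_frac = 0.7, width = 0.3,
                 downshift = 1.5, n_perm = 250,
                 contrast = c("C", "NMN"), anova_q = 0.01)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [pipeline_config()];
#' unknown keys at either level are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop_arg("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (!is.list(cfg[[sec]])) { cfg[[sec]] <- user[[sec]]; next }
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop_arg("unknown key(s) in section '%s': %s", sec,
               paste(bad, collapse = ", "))
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- unlist(user[[sec]][[k]])
  }
  cfg
}

# stable small hash of the resolved configuration, for the audit log
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis chain on synthetic data
#'
#' Chains simulate -> classify -> spatial -> statistics and writes every
#' intermediate artifact plus a machine-readable `summary.json` into
#' `out_dir`. Deterministic for a fixed configuration: the same seed
#' yields byte-identical summaries. Planted truth: a set of marker
#' proteins carries a group fold-change in the first contrast group; ten
#' of the markers are "DMBT1-like", i.e. down-regulated there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return the summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, fmt, ...)
    message(sprintf("[dvpflow:%s] %s", stage, sprintf(fmt, ...)))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline aborted in stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed
  log_msg("config", "seed=%d hash=%s", seed, config_hash(config))

  ## --- simulate ----------------------------------------------------------
  sim <- config$simulate
  nuc <- run_stage("simulate", gen_nuclei_table(
    sim$n_cells, default_class_params(sim$mix_weights),
    outlier_fraction = sim$outlier_fraction,
    image_size_px = sim$image_size_px, seed = seed))
  regions <- run_stage("simulate", gen_regions(
    n_regions = sim$n_regions, image_size_px = sim$image_size_px,
    seed = seed, um_per_px = config$classify$um_per_px))
  design <- default_design()
  n_mark <- sim$n_markers
  markers <- effect_spec(
    protein_id = c(sprintf("MARKER_UP_%02d", seq_len(ceiling(n_mark / 2))),
                   sprintf("MARKER_DN_%02d", seq_len(floor(n_mark / 2)))),
    group = config$stats$contrast[1],
    log2_fc = c(rep(sim$marker_log2_fc, ceiling(n_mark / 2)),
                rep(-sim$marker_log2_fc, floor(n_mark / 2))))
  pm <- run_stage("simulate", gen_protein_matrix(
    design, sim$n_proteins, base_log2_mean = sim$base_log2_mean,
    base_log2_sd = sim$base_log2_sd, effects = markers,
    noise_sd = sim$noise_sd,
    missing = missingness_spec(sim$missing_slope, sim$missing_midpoint,
                               sim$missing_floor, sim$missing_ceiling),
    seed = seed))
  write_nuclei_csv(nuc, file.path(out_dir, "nuclei.csv"))
  write_regions_geojson(regions, file.path(out_dir, "regions.geojson"))
  # on-disk pg_matrix carries linear intensities, as DIA search output does
  write_matrix(as_linear(pm$matrix), file.path(out_dir, "pg_matrix.tsv"))
  write_design(design, file.path(out_dir, "design.tsv"))
  utils::write.table(pm$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_msg("simulate", "%d cells, %d regions, %d proteins x %d samples",
          nrow(nuc), length(regions$regions), nrow(pm$matrix$values),
          ncol(pm$matrix$values))

  ## --- classify ----------------------------------------------------------
  ccfg <- do.call(classifier_config, config$classify)
  cells <- run_stage("classify", classify_cells(nuc, ccfg))
  write_classified_csv(cells, file.path(out_dir, "classified.csv"))
  class_counts <- table(factor(cells$assigned_class,
                               c("CDX2++", "CDX2+", "CDX2-",
                                 "unclassified")))
  log_msg("classify", "%d outliers removed; classes: %s",
          sum(cells$outlier),
          paste(sprintf("%s=%d", names(class_counts), class_counts),
                collapse = " "))

  ## --- spatial -----------------------------------------------------------
  sp <- config$spatial
  cells <- run_stage("spatial", assign_regions(cells, regions))
  dist_tab <- run_stage("spatial", class_region_distribution(cells))
  utils::write.csv(cbind(class = rownames(dist_tab), round(dist_tab, 3)),
                   file.path(out_dir, "class_region_distribution.csv"),
                   row.names = FALSE)
  pools <- run_stage("spatial", sample_shapes(
    cells, per_class = sp$per_class, replicates = sp$replicates,
    seed = seed, allow_fewer = sp$allow_fewer))
  utils::write.csv(pools, file.path(out_dir, "well_assignments.csv"),
                   row.names = FALSE)
  # cut contours for the first collected pool, dilated by the cutting offset
  pool1 <- pools[pools$class == pools$class[1] & pools$replicate == 1, ]
  contours <- run_stage("spatial", cell_contours(
    cells[match(pool1$cell_id, cells$cell_id), ],
    n_vertices = sp$contour_vertices, um_per_px = ccfg$um_per_px))
  contours$wells <- stats::setNames(pool1$well,
                                    vapply(contours$shapes, `[[`,
                                           character(1), "shape_id"))
  contours <- run_stage("spatial", dilate_contours(
    contours, offset_um = sp$offset_um, um_per_px = ccfg$um_per_px))
  calib <- rbind(c(0, 0), c(sim$image_size_px[1], 0),
                 c(0, sim$image_size_px[2]))
  run_stage("spatial", export_lmd(contours, calib,
                                  file.path(out_dir, "contours_lmd.xml")))
  log_msg("spatial", "%d shapes pooled into %d wells; %d contours exported",
          nrow(pools), length(unique(pools$well)),
          length(contours$shapes))

  ## --- stats -------------------------------------------------------------
  st <- config$stats
  filt <- run_stage("stats", filter_valid_values(pm$matrix, design,
                                                 min_frac = st$min_frac))
  imp <- run_stage("stats", impute_mnar(filt, width = st$width,
                                        downshift = st$downshift,
                                        seed = seed))
  tt <- run_stage("stats", permutation_fdr(
    imp$matrix, design, test = "ttest", group_a = st$contrast[1],
    group_b = st$contrast[2], s0 = st$s0, n_perm = st$n_perm, q = st$q,
    seed = seed))
  av <- run_stage("stats", permutation_fdr(
    imp$matrix, design, test = "anova", s0 = st$s0, n_perm = st$n_perm,
    q = st$anova_q, seed = seed))
  cv <- run_stage("stats", cv_table(as_linear(filt), design))
  pca <- run_stage("stats", pca_matrix(imp$matrix))
  rank_tab <- run_stage("stats", rank_abundance(
    filt, design, group = st$contrast[1],
    highlight = intersect(pm$truth$protein_id, rownames(filt$values))))
  utils::write.table(tt, file.path(out_dir, "ttest_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(av, file.path(out_dir, "anova_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(protein = rownames(cv$cv), cv$cv),
                     file.path(out_dir, "cv_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rank_tab, file.path(out_dir, "rank_abundance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_msg("stats", "%d/%d proteins pass filter; %d t-test and %d ANOVA hits",
          nrow(filt$values), nrow(pm$matrix$values), sum(tt$significant),
          sum(av$significant))

  ## --- summary -----------------------------------------------------------
  summary <- list(
    seed = seed,
    config_hash = config_hash(config),
    cells_in = nrow(nuc),
    outliers_removed = sum(cells$outlier),
    class_counts = as.list(stats::setNames(as.integer(class_counts),
                                           names(class_counts))),
    regions = names(regions$regions),
    distribution_pct = lapply(seq_len(nrow(dist_tab)), function(i)
      stats::setNames(as.list(round(as.numeric(dist_tab[i, ]), 4)),
                      colnames(dist_tab))),
    shapes_sampled = nrow(pools),
    wells_used = length(unique(pools$well)),
    proteins_in = nrow(pm$matrix$values),
    proteins_filtered = nrow(filt$values),
    values_imputed = sum(imp$mask),
    significant_ttest = sum(tt$significant),
    significant_anova = sum(av$significant),
    median_cv_pct = as.list(round(cv$median_cv, 4)),
    pc1_variance_pct = round(unname(pca$variance_explained[1]), 4),
    markers_recovered = sum(tt$significant[tt$protein %in%
                                             pm$truth$protein_id]))
  names(summary$distribution_pct) <- rownames(dist_tab)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(summary, dist_tab, tt, rank_tab,
               file.path(out_dir, "report.txt"))
  invisible(summary)
}

# plain-text run report: stage counts, the class-by-region distribution
# table and the top differential hits
write_report <- function(summary, dist_tab, tt, rank_tab, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
  w("dvpflow run report (seed %d, config %s)", summary$seed,
    summary$config_hash)
  w("cells: %d in, %d outliers removed", summary$cells_in,
    summary$outliers_removed)
  w("class counts: %s",
    paste(sprintf("%s=%d", names(summary$class_counts),
                  unlist(summary$class_counts)), collapse = "  "))
  w("")
  w("class-by-region distribution (%% of class, rounded):")
  disp <- attr(dist_tab, "display")
  for (cl in rownames(disp))
    w("  %-12s %s", cl,
      paste(sprintf("%s=%s%%", colnames(disp), disp[cl, ]), collapse = "  "))
  w("  (percentages are rounded and may not add up to 100%%)")
  w("")
  w("shapes sampled: %d into %d wells", summary$shapes_sampled,
    summary$wells_used)
  w("proteins: %d in, %d after valid-value filter, %d values imputed",
    summary$proteins_in, summary$proteins_filtered, summary$values_imputed)
  w("significant: %d (t test), %d (ANOVA); planted markers recovered: %d",
    summary$significant_ttest, summary$significant_anova,
    summary$markers_recovered)
  w("")
  top <- utils::head(tt[order(tt$q_value, -abs(tt$d_stat)), ], 10)
  w("top differential proteins (t test):")
  for (i in seq_len(nrow(top)))
    w("  %-14s log2fc=%+.3f d=%+.3f q=%.4f", top$protein[i],
      top$log2_fc[i], top$d_stat[i], top$q_value[i])
  invisible(path)
}
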