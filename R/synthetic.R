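#' Per-class distribution parameters for synthetic nuclei
#'
#' Describes one nuclear phenotype class by the distributions of its image
#' features: mean RGB intensities (brightfield, 0-255), nuclear area
#' (pixels squared) and eccentricity. Draws are Gaussian, with eccentricity
#' clipped to `[0, 1)` and area to a small positive floor.
#'
#' @param class_name class label, e.g. `"CDX2++"`.
#' @param rgb_mean numeric 3-vector of mean channel intensities in `[0, 255]`.
#' @param rgb_sd numeric 3-vector of channel standard deviations (>= 0).
#' @param area_mean_px2,area_sd nuclear area moments in pixels squared.
#' @param ecc_mean,ecc_sd eccentricity moments, dimensionless in `[0, 1)`.
#' @param mix_weight mixture fraction of this class in `[0, 1]`.
#' @return an object of class `"class_params"` (a validated list).
#' @seealso [default_class_params()], [gen_nuclei_table()]
#' @export
class_params <- function(class_name, rgb_mean, rgb_sd, area_mean_px2,
                         area_sd, ecc_mean, ecc_sd, mix_weight) {
  if (!is.character(class_name) || length(class_name) != 1L)
    stop_arg("'class_name' must be a single string")
  rgb_mean <- as.numeric(rgb_mean); rgb_sd <- as.numeric(rgb_sd)
  if (length(rgb_mean) != 3L || any(rgb_mean < 0) || any(rgb_mean > 255))
    stop_arg("'rgb_mean' must be a 3-vector in [0, 255]")
  if (length(rgb_sd) != 3L || any(rgb_sd < 0))
    stop_arg("'rgb_sd' must be a non-negative 3-vector")
  if (area_mean_px2 <= 0 || area_sd < 0)
    stop_arg("area parameters must be positive")
  if (ecc_mean < 0 || ecc_mean >= 1 || ecc_sd < 0)
    stop_arg("'ecc_mean' must lie in [0, 1)")
  if (mix_weight < 0 || mix_weight > 1)
    stop_arg("'mix_weight' must lie in [0, 1]")
  structure(list(class_name = class_name, rgb_mean = rgb_mean,
                 rgb_sd = rgb_sd, area_mean_px2 = area_mean_px2,
                 area_sd = area_sd, ecc_mean = ecc_mean, ecc_sd = ecc_sd,
                 mix_weight = mix_weight),
            class = "class_params")
}

#' Default synthetic class parameters for DAB/hematoxylin brightfield nuclei
#'
#' Three classes emulating CDX2 immunohistochemistry: `CDX2++` strongly
#' DAB-brown (red-dominant), `CDX2+` intermediate, and `CDX2-`
#' hematoxylin-blue stromal nuclei that are smaller (about 60% of the
#' epithelial area) and more eccentric (mean 0.8 vs 0.55), reflecting the
#' elongated fibroblast/lymphocyte morphology that distinguishes stroma
#' from round columnar epithelial nuclei. These are generator defaults, not
#' estimates fitted to any particular data set.
#'
#' @param mix_weights numeric 3-vector of class fractions summing to 1
#'   (order: CDX2++, CDX2+, CDX2-).
#' @return list of three [class_params()] objects.
#' @export
default_class_params <- function(mix_weights = c(0.3, 0.3, 0.4)) {
  if (length(mix_weights) != 3L || abs(sum(mix_weights) - 1) > 1e-9)
    stop_arg("'mix_weights' must be a 3-vector summing to 1")
  list(
    class_params("CDX2++", rgb_mean = c(165, 110, 60), rgb_sd = c(6, 6, 6),
                 area_mean_px2 = 220, area_sd = 40,
                 ecc_mean = 0.55, ecc_sd = 0.10, mix_weight = mix_weights[1]),
    class_params("CDX2+", rgb_mean = c(150, 120, 100), rgb_sd = c(6, 6, 6),
                 area_mean_px2 = 220, area_sd = 40,
                 ecc_mean = 0.55, ecc_sd = 0.10, mix_weight = mix_weights[2]),
    class_params("CDX2-", rgb_mean = c(90, 85, 140), rgb_sd = c(6, 6, 6),
                 area_mean_px2 = 132, area_sd = 20,
                 ecc_mean = 0.80, ecc_sd = 0.07, mix_weight = mix_weights[3])
  )
}

#' Generate a synthetic segmented-nuclei feature table
#'
#' Emulates the per-nucleus feature matrix exported by an image segmentation
#' tool: centroid coordinates uniform over the image, and class-conditional
#' Gaussian features per [class_params()]. A seeded `outlier_fraction`
#' subset of nuclei is drawn with channel standard deviations inflated
#' five-fold, emulating staining artifacts and debris so that downstream
#' intensity-outlier removal has something real to remove.
#'
#' @param n_cells number of nuclei (>= 0).
#' @param class_params list of [class_params()]; mixture weights must sum
#'   to 1.
#' @param outlier_fraction fraction of nuclei drawn from the
#'   inflated-variance artifact mixture.
#' @param image_size_px integer pair, image width and height in pixels
#'   (origin top-left, y increases downward).
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @param image_id image identifier stored in every row.
#' @return `data.frame` with columns `cell_id`, `image_id`, `x_px`, `y_px`,
#'   `area_px2`, `eccentricity`, `mean_r`, `mean_g`, `mean_b`, plus the
#'   planted truth `true_class` and `true_outlier`.
#' @export
#' @examples
#' nuc <- gen_nuclei_table(100, seed = 1)
#' table(nuc$true_class)
gen_nuclei_table <- function(n_cells, class_params = default_class_params(),
                             outlier_fraction = 0.05,
                             image_size_px = c(2000, 2000), seed,
                             image_id = "img1") {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0)
    stop_arg("'n_cells' must be a single non-negative number")
  if (missing(seed)) stop_arg("'seed' is required")
  w <- vapply(class_params, function(p) p$mix_weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9)
    stop_arg("class mix weights must sum to 1 (got %.6f)", sum(w))
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_arg("'outlier_fraction' must lie in [0, 1)")
  cls <- vapply(class_params, function(p) p$class_name, character(1))

  empty <- data.frame(cell_id = character(), image_id = character(),
                      x_px = numeric(), y_px = numeric(),
                      area_px2 = numeric(), eccentricity = numeric(),
                      mean_r = numeric(), mean_g = numeric(),
                      mean_b = numeric(), true_class = character(),
                      true_outlier = logical(), stringsAsFactors = FALSE)
  n_cells <- as.integer(n_cells)
  if (n_cells == 0L) return(empty)

  set.seed(derive_seed(seed, "nuclei"))
  k <- sample.int(length(cls), n_cells, replace = TRUE, prob = w)
  is_out <- runif(n_cells) < outlier_fraction
  x <- runif(n_cells, 0, image_size_px[1])
  y <- runif(n_cells, 0, image_size_px[2])

  area <- ecc <- mr <- mg <- mb <- numeric(n_cells)
  for (j in seq_along(cls)) {
    idx <- which(k == j)
    if (!length(idx)) next
    p <- class_params[[j]]
    infl <- ifelse(is_out[idx], 5, 1)
    area[idx] <- pmax(1, rnorm(length(idx), p$area_mean_px2, p$area_sd))
    ecc[idx] <- pmin(0.999, pmax(0, rnorm(length(idx), p$ecc_mean, p$ecc_sd)))
    mr[idx] <- rnorm(length(idx), p$rgb_mean[1], p$rgb_sd[1] * infl)
    mg[idx] <- rnorm(length(idx), p$rgb_mean[2], p$rgb_sd[2] * infl)
    mb[idx] <- rnorm(length(idx), p$rgb_mean[3], p$rgb_sd[3] * infl)
  }
  clip255 <- function(v) pmin(255, pmax(0, v))
  data.frame(cell_id = sprintf("cell_%06d", seq_len(n_cells)),
             image_id = image_id, x_px = x, y_px = y, area_px2 = area,
             eccentricity = ecc, mean_r = clip255(mr), mean_g = clip255(mg),
             mean_b = clip255(mb), true_class = cls[k],
             true_outlier = is_out, stringsAsFactors = FALSE)
}

#' Write / read the nuclei feature CSV dialect
#'
#' Fixed header: `cell_id, image_id, x_px, y_px, area_px2, eccentricity,
#' mean_r, mean_g, mean_b, true_class` (the truth column is written as
#' empty strings when unknown).
#'
#' @param table nuclei `data.frame` as from [gen_nuclei_table()].
#' @param path file path.
#' @return `read_nuclei_csv` returns the table; `write_nuclei_csv` its path,
#'   invisibly.
#' @export
write_nuclei_csv <- function(table, path) {
  cols <- c("cell_id", "image_id", "x_px", "y_px", "area_px2",
            "eccentricity", "mean_r", "mean_g", "mean_b")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop_arg("nuclei table lacks columns: %s",
             paste(missing_cols, collapse = ", "))
  out <- table[, cols, drop = FALSE]
  out$true_class <- if ("true_class" %in% names(table)) table$true_class else ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nuclei_csv
#' @export
read_nuclei_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Logistic missing-not-at-random specification
#'
#' Probability that a log2 intensity `x` is missing:
#' `clip(plogis(slope * (x - midpoint)), floor, ceiling)`. A negative slope
#' makes low-abundance proteins more likely to be missing, the MNAR
#' structure that downshifted-normal imputation assumes.
#'
#' @param slope logistic slope per log2 unit (<= 0 for MNAR).
#' @param midpoint log2 intensity at which the unclipped probability is 0.5.
#' @param floor,ceiling probability clip bounds in `[0, 1]`, `floor <=
#'   ceiling`.
#' @return an object of class `"missingness_spec"`.
#' @export
missingness_spec <- function(slope = -0.8, midpoint = 17, floor = 0,
                             ceiling = 0.6) {
  if (floor < 0 || ceiling > 1 || floor > ceiling)
    stop_arg("need 0 <= floor <= ceiling <= 1")
  structure(list(slope = slope, midpoint = midpoint, floor = floor,
                 ceiling = ceiling), class = "missingness_spec")
}

#' Planted group effects for the protein-matrix generator
#'
#' @param protein_id protein identifiers.
#' @param group group label the effect applies to.
#' @param log2_fc signed log2 fold-change of that protein in that group
#'   relative to the grand baseline.
#' @return `data.frame` with one row per (protein, group) effect.
#' @export
effect_spec <- function(protein_id, group, log2_fc) {
  d <- data.frame(protein_id = as.character(protein_id),
                  group = as.character(group),
                  log2_fc = as.numeric(log2_fc), stringsAsFactors = FALSE)
  if (any(!is.finite(d$log2_fc))) stop_arg("'log2_fc' must be finite")
  if (anyDuplicated(d[, c("protein_id", "group")]))
    stop_arg("each (protein, group) pair may appear at most once")
  d
}

#' Default sample design: 3 outcome groups x 3 patients x 3 replicates
#'
#' Mirrors a cohort of three outcome groups (C = metachronous cancer,
#' HDA = metachronous high-grade dysplasia adenoma, NMN = non-metachronous
#' neoplasms), three patients per group and triplicate measurements,
#' 27 samples in total.
#'
#' @param groups group labels.
#' @param n_patients patients per group.
#' @param n_replicates replicates per patient.
#' @return design `data.frame` with columns `sample`, `group`, `patient`,
#'   `replicate`.
#' @export
default_design <- function(groups = c("C", "HDA", "NMN"), n_patients = 3,
                           n_replicates = 3) {
  d <- expand.grid(replicate = seq_len(n_replicates),
                   patient = seq_len(n_patients), group = groups,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(sample = sprintf("%s_P%d_R%d", d$group, d$patient, d$replicate),
             group = d$group,
             patient = sprintf("%s_P%d", d$group, d$patient),
             replicate = d$replicate, stringsAsFactors = FALSE)
}

#' Generate a synthetic protein-group intensity matrix with planted truth
#'
#' Log2 intensities are `baseline_p + effect_{p,g} + N(0, noise_sd)`, with
#' per-protein baselines `N(base_log2_mean, base_log2_sd)`. Entries are then
#' censored missing-not-at-random according to a logistic model of the
#' log2 intensity ([missingness_spec()]).
#'
#' @param design design table as from [default_design()]; needs >= 2 groups
#'   with >= 2 samples each.
#' @param n_proteins number of protein groups (> 0).
#' @param base_log2_mean,base_log2_sd baseline log2 abundance distribution.
#' @param effects `data.frame` from [effect_spec()], or `NULL`.
#' @param noise_sd replicate-level log2 noise standard deviation.
#' @param missing a [missingness_spec()]; use `floor = ceiling = 0` for a
#'   complete matrix.
#' @param seed integer seed.
#' @return list with `matrix` (an [intensity_matrix()] on log2 scale, `NA`
#'   for missing), `truth` (planted effects per protein and group) and
#'   `design`.
#' @export
gen_protein_matrix <- function(design, n_proteins, base_log2_mean = 22,
                               base_log2_sd = 2.5, effects = NULL,
                               noise_sd = 0.5,
                               missing = missingness_spec(), seed) {
  if (missing(seed)) stop_arg("'seed' is required")
  if (!is.numeric(n_proteins) || n_proteins <= 0)
    stop_arg("'n_proteins' must be a positive count")
  ng <- table(design$group)
  if (length(ng) < 2L || any(ng < 2L))
    stop_arg("design needs >= 2 groups with >= 2 samples each")
  n_proteins <- as.integer(n_proteins)
  prot <- sprintf("P%05d", seq_len(n_proteins))
  if (!is.null(effects) && nrow(effects)) {
    # named markers not of the form P%05d take over the first protein slots
    unknown <- setdiff(unique(effects$protein_id), prot)
    if (length(unknown) > n_proteins)
      stop_arg("more named marker proteins than 'n_proteins'")
    prot[seq_along(unknown)] <- unknown
    bad_group <- setdiff(effects$group, unique(design$group))
    if (length(bad_group))
      stop_arg("effect group(s) not in design: %s",
               paste(bad_group, collapse = ", "))
  }

  set.seed(derive_seed(seed, "protein_matrix"))
  base <- rnorm(n_proteins, base_log2_mean, base_log2_sd)
  ns <- nrow(design)
  eff <- matrix(0, n_proteins, ns, dimnames = list(prot, design$sample))
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      p <- match(effects$protein_id[i], prot)
      if (is.na(p)) next
      eff[p, design$group == effects$group[i]] <- effects$log2_fc[i]
    }
  }
  x <- base + eff + matrix(rnorm(n_proteins * ns, 0, noise_sd),
                           n_proteins, ns)
  dimnames(x) <- list(prot, design$sample)

  p_miss <- stats::plogis(missing$slope * (x - missing$midpoint))
  p_miss <- pmin(missing$ceiling, pmax(missing$floor, p_miss))
  x[matrix(runif(length(x)), nrow(x)) < p_miss] <- NA_real_

  truth <- if (is.null(effects) || !nrow(effects)) {
    data.frame(protein_id = character(), group = character(),
               log2_fc = numeric(), stringsAsFactors = FALSE)
  } else effects[effects$protein_id %in% prot, , drop = FALSE]
  mat <- intensity_matrix(x, genes = prot, scale = "log2")
  list(matrix = mat, truth = truth, design = design)
}
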