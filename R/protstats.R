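#' Filter proteins by valid values in at least one group
#'
#' A protein group is kept when at least one sample group quantifies it in
#' at least `ceil(min_frac * n_g)` of its `n_g` samples — the classic
#' "70% valid in at least one group" rule of proteomics differential
#' analysis. With triplicates this requires all 3 values (2/3 is 66.7%,
#' below 70%). Row order is preserved and the filter is idempotent.
#'
#' @param x an [intensity_matrix()] (only missingness is inspected).
#' @param design design table matching the matrix columns.
#' @param min_frac required fraction of valid values within a group.
#' @param mode only `"in_at_least_one_group"` is defined.
#' @return the filtered [intensity_matrix()].
#' @export
filter_valid_values <- function(x, design, min_frac = 0.7,
                                mode = "in_at_least_one_group") {
  if (!identical(mode, "in_at_least_one_group"))
    stop_arg("unknown filtering mode '%s'", mode)
  if (min_frac < 0 || min_frac > 1) stop_arg("'min_frac' must be in [0, 1]")
  design <- check_design(x, design, min_per_group = 1L)
  keep <- rep(FALSE, nrow(x$values))
  for (g in unique(design$group)) {
    cols <- design$sample[design$group == g]
    need <- ceiling(min_frac * length(cols))
    keep <- keep |
      rowSums(!is.na(x$values[, cols, drop = FALSE])) >= need
  }
  x[keep, ]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Perseus-style imputation for missing-not-at-random label-free data: for
#' each sample column with observed mean `m` and standard deviation `s`,
#' missing entries are drawn from `Normal(m - downshift * s,
#' (width * s)^2)` — a narrow distribution shifted into the low-abundance
#' tail, where values censored by the detection limit are expected to lie.
#' Observed entries are never altered.
#'
#' @param x an [intensity_matrix()] on the log2 scale.
#' @param width imputation width as a multiple of `s` (default 0.3).
#' @param downshift shift in multiples of `s` (default 1.5).
#' @param per_column per-sample moments (default); `FALSE` uses the
#'   whole-matrix mean and standard deviation.
#' @param seed integer seed; identical seeds give identical imputations.
#' @return list with `matrix` (imputed [intensity_matrix()]) and `mask`
#'   (logical matrix, `TRUE` where a value was imputed).
#' @export
impute_mnar <- function(x, width = 0.3, downshift = 1.5, per_column = TRUE,
                        seed) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale != "log2")
    stop_arg("imputation operates on the log2 scale (got '%s')", x$scale)
  if (missing(seed)) stop_arg("'seed' is required")
  vals <- x$values
  mask <- is.na(vals)
  set.seed(derive_seed(seed, "impute"))
  if (per_column) {
    for (j in seq_len(ncol(vals))) {
      obs <- vals[!mask[, j], j]
      if (sum(!mask[, j]) < 2L)
        stop_arg("imputation error: column '%s' has fewer than 2 observed values",
                 colnames(vals)[j])
      nmis <- sum(mask[, j])
      if (nmis)
        vals[mask[, j], j] <- rnorm(nmis, mean(obs) - downshift * sd(obs),
                                    width * sd(obs))
    }
  } else {
    obs <- vals[!mask]
    if (length(obs) < 2L)
      stop_arg("imputation error: fewer than 2 observed values in the matrix")
    vals[mask] <- rnorm(sum(mask), mean(obs) - downshift * sd(obs),
                        width * sd(obs))
  }
  list(matrix = intensity_matrix(vals, genes = x$genes, scale = "log2"),
       mask = mask)
}

# ---- moderated statistics -------------------------------------------------

# vectorized s0-moderated two-sample statistic on a plain value matrix
tstat_core <- function(vals, ia, ib, s0) {
  na <- length(ia); nb <- length(ib)
  xa <- rowMeans(vals[, ia, drop = FALSE])
  xb <- rowMeans(vals[, ib, drop = FALSE])
  ssa <- rowSums((vals[, ia, drop = FALSE] - xa)^2)
  ssb <- rowSums((vals[, ib, drop = FALSE] - xb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  list(fc = xa - xb, d = (xa - xb) / (se + s0), se = se,
       mean_a = xa, mean_b = xb)
}

# vectorized s0-moderated one-way statistic; idx is a list of column index
# vectors, one per group
fstat_core <- function(vals, idx, s0) {
  k <- length(idx)
  n <- sum(lengths(idx))
  gm <- rowMeans(vals)
  ssb <- 0; ssw <- 0
  means <- matrix(NA_real_, nrow(vals), k)
  for (g in seq_len(k)) {
    mg <- rowMeans(vals[, idx[[g]], drop = FALSE])
    means[, g] <- mg
    ssb <- ssb + length(idx[[g]]) * (mg - gm)^2
    ssw <- ssw + rowSums((vals[, idx[[g]], drop = FALSE] - mg)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  list(f = msb / (sqrt(msw) + s0)^2, means = means)
}

#' s0-moderated two-sample t statistic
#'
#' The SAM-style moderated statistic `d = (mean_a - mean_b) /
#' (se_pooled + s0)`, where `se_pooled` is the usual pooled-variance
#' two-sample standard error and the fudge constant `s0` damps the
#' significance of proteins with near-zero variance. With `s0 = 0` this is
#' exactly the classical pooled t statistic.
#'
#' @param x an [intensity_matrix()] without missing values (run after
#'   [impute_mnar()]).
#' @param design design table.
#' @param group_a,group_b group labels to contrast (difference is
#'   `a - b`).
#' @param s0 fudge constant on the standard-error scale (default 0.1).
#' @return `data.frame` with `protein`, `log2_fc`, `d_stat`, `se`,
#'   `mean_a`, `mean_b`.
#' @export
s0_tstat <- function(x, design, group_a, group_b, s0 = 0.1) {
  design <- check_design(x, design)
  if (anyNA(x$values))
    stop_arg("matrix contains missing values; filter and impute first")
  for (g in c(group_a, group_b))
    if (!g %in% design$group) stop_arg("group '%s' not in design", g)
  ia <- which(design$group == group_a)
  ib <- which(design$group == group_b)
  r <- tstat_core(x$values, ia, ib, s0)
  undef <- r$se == 0 & s0 == 0
  if (any(undef)) {
    warning(sprintf("%d protein(s) have zero variance in both groups and s0 = 0; statistic undefined, emitted as NA",
                    sum(undef)))
    r$d[undef] <- NA_real_
  }
  data.frame(protein = rownames(x$values), log2_fc = r$fc, d_stat = r$d,
             se = r$se, mean_a = r$mean_a, mean_b = r$mean_b,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' s0-moderated one-way ANOVA statistic
#'
#' `F' = MSB / (sqrt(MSW) + s0)^2` with the usual between- and
#' within-group mean squares; `s0 = 0` recovers the classical one-way F
#' statistic, and a positive `s0` keeps the statistic finite for proteins
#' with zero within-group variance.
#'
#' @inheritParams s0_tstat
#' @return `data.frame` with `protein`, `d_stat` (the moderated F) and one
#'   `mean_<group>` column per group.
#' @export
anova_s0 <- function(x, design, s0 = 0.1) {
  design <- check_design(x, design)
  if (anyNA(x$values))
    stop_arg("matrix contains missing values; filter and impute first")
  groups <- unique(design$group)
  if (length(groups) < 2L) stop_arg("ANOVA needs >= 2 groups")
  idx <- lapply(groups, function(g) which(design$group == g))
  r <- fstat_core(x$values, idx, s0)
  out <- data.frame(protein = rownames(x$values), d_stat = r$f,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in seq_along(groups)) out[[paste0("mean_", groups[g])]] <- r$means[, g]
  out
}

#' SAM-style permutation-based false discovery rate
#'
#' Recomputes the moderated statistic under `n_perm` seeded permutations
#' of the sample-to-group labels. For each candidate cutoff `delta` among
#' the observed `|d|` values, the estimated FDR is the mean permutation
#' count of `|d*| >= delta` divided by the observed count at the same
#' cutoff (pi0 fixed at 1, conservative), capped at 1 and made monotone
#' non-increasing in `delta`; each protein's q-value is the monotonized
#' FDR at its own `|d|`, so a larger `|d|` never has a larger q-value.
#'
#' @param x an [intensity_matrix()] without missing values.
#' @param design design table.
#' @param test `"ttest"` ([s0_tstat()] on `group_a` vs `group_b`) or
#'   `"anova"` ([anova_s0()] across all groups).
#' @param group_a,group_b groups contrasted when `test = "ttest"`.
#' @param s0 fudge constant.
#' @param n_perm number of label permutations (default 250).
#' @param q FDR threshold for the significance call (default 0.05).
#' @param seed integer seed.
#' @return `data.frame` (one row per protein): `protein`, `log2_fc`
#'   (`NA` for ANOVA), `d_stat`, `q_value`, `significant`, plus group
#'   means.
#' @export
permutation_fdr <- function(x, design, test = c("ttest", "anova"),
                            group_a = NULL, group_b = NULL, s0 = 0.1,
                            n_perm = 250, q = 0.05, seed) {
  test <- match.arg(test)
  if (missing(seed)) stop_arg("'seed' is required")
  if (n_perm < 1) stop_arg("'n_perm' must be >= 1")
  design <- check_design(x, design)
  if (anyNA(x$values))
    stop_arg("matrix contains missing values; filter and impute first")

  if (test == "ttest") {
    if (is.null(group_a) || is.null(group_b))
      stop_arg("'group_a' and 'group_b' are required for the t test")
    keep <- design$group %in% c(group_a, group_b)
    design <- design[keep, , drop = FALSE]
    vals <- x$values[, design$sample, drop = FALSE]
    ia <- which(design$group == group_a)
    ib <- which(design$group == group_b)
    if (choose(length(ia) + length(ib), length(ia)) <= 1)
      stop_arg("groups too small for any distinct permutation; use exact enumeration")
    obs <- tstat_core(vals, ia, ib, s0)
    res <- data.frame(protein = rownames(vals), log2_fc = obs$fc,
                      d_stat = obs$d, stringsAsFactors = FALSE,
                      row.names = NULL)
    res[[paste0("mean_", group_a)]] <- obs$mean_a
    res[[paste0("mean_", group_b)]] <- obs$mean_b
    perm_stat <- function() {
      sh <- sample.int(ncol(vals))
      abs(tstat_core(vals, sh[seq_along(ia)],
                     sh[length(ia) + seq_along(ib)], s0)$d)
    }
  } else {
    vals <- x$values[, design$sample, drop = FALSE]
    groups <- unique(design$group)
    idx <- lapply(groups, function(g) which(design$group == g))
    if (length(groups) < 2L) stop_arg("ANOVA needs >= 2 groups")
    if (choose(ncol(vals), length(idx[[1]])) <= 1)
      stop_arg("groups too small for any distinct permutation; use exact enumeration")
    obs_f <- fstat_core(vals, idx, s0)
    res <- data.frame(protein = rownames(vals), log2_fc = NA_real_,
                      d_stat = obs_f$f, stringsAsFactors = FALSE,
                      row.names = NULL)
    for (g in seq_along(groups))
      res[[paste0("mean_", groups[g])]] <- obs_f$means[, g]
    perm_stat <- function() {
      sh <- sample.int(ncol(vals))
      pidx <- idx
      off <- 0L
      for (g in seq_along(idx)) {
        pidx[[g]] <- sh[off + seq_along(idx[[g]])]
        off <- off + length(idx[[g]])
      }
      abs(fstat_core(vals, pidx, s0)$f)
    }
  }

  absd <- abs(res$d_stat)
  absd[is.na(absd)] <- 0          # undefined statistics are never called
  set.seed(derive_seed(seed, "permutation_fdr"))
  perm_sorted <- sort(unlist(lapply(seq_len(n_perm),
                                    function(b) perm_stat())))
  obs_sorted <- sort(absd)
  n_prot <- length(absd)
  # counts at cutoff |d_i|: #{v >= t} = n - #{v < t}
  v_ge <- (length(perm_sorted) -
             findInterval(absd, perm_sorted, left.open = TRUE)) / n_perm
  r_ge <- n_prot - findInterval(absd, obs_sorted, left.open = TRUE)
  raw <- pmin(1, v_ge / pmax(1, r_ge))
  ord <- order(absd, decreasing = TRUE)
  qv <- numeric(n_prot)
  qv[ord] <- rev(cummin(rev(raw[ord])))   # monotone non-increasing in |d|
  res$q_value <- qv
  res$significant <- qv <= q
  res
}

#' Per-protein, per-group coefficients of variation
#'
#' `CV = 100 * sd / mean` over the valid (unimputed) linear-scale values
#' of each group; groups with fewer than two valid values give `NA`.
#' CVs are meaningful only on unimputed linear intensities — imputation
#' would artificially deflate replicate variability.
#'
#' @param x an [intensity_matrix()] on the linear scale.
#' @param design design table.
#' @return list with `cv` (proteins x groups percent matrix) and
#'   `median_cv` (per-group median, `NA` removed).
#' @export
cv_table <- function(x, design) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale != "linear")
    stop_arg("CVs are computed on the linear scale (got '%s')", x$scale)
  if (any(x$values < 0, na.rm = TRUE))
    stop_arg("negative linear intensities are not allowed")
  design <- check_design(x, design, min_per_group = 1L)
  groups <- unique(design$group)
  cv <- matrix(NA_real_, nrow(x$values), length(groups),
               dimnames = list(rownames(x$values), groups))
  for (g in groups) {
    sub <- x$values[, design$sample[design$group == g], drop = FALSE]
    nvalid <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, stats::sd, na.rm = TRUE)
    cvg <- 100 * s / m
    cvg[nvalid < 2L] <- NA_real_
    cv[, g] <- cvg
  }
  list(cv = cv, median_cv = apply(cv, 2, stats::median, na.rm = TRUE))
}

#' Row-wise z-scoring (standardization)
#'
#' Centers every protein row to mean 0 and scales to standard deviation 1,
#' the standardization conventionally applied before heatmap clustering.
#' Constant rows become all zeros with a warning.
#'
#' @param x an [intensity_matrix()] or numeric matrix without missing
#'   values.
#' @return same type as the input.
#' @export
zscore_rows <- function(x) {
  vals <- if (inherits(x, "intensity_matrix")) x$values else x
  if (anyNA(vals)) stop_arg("missing values present; impute first")
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  flat <- s == 0
  if (any(flat)) {
    warning(sprintf("%d constant row(s) z-scored to all zeros", sum(flat)))
    s[flat] <- 1
  }
  z <- (vals - m) / s
  if (inherits(x, "intensity_matrix"))
    intensity_matrix(z, genes = x$genes, scale = x$scale)
  else z
}

#' Hierarchical clustering of proteins and samples
#'
#' Agglomerative clustering (via [stats::hclust()]) of the rows and
#' columns of the matrix, defaulting to Euclidean distance with average
#' linkage on (typically row-z-scored) values.
#'
#' @param x an [intensity_matrix()] or numeric matrix without missing
#'   values, >= 2 rows.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"maximum"`.
#' @param linkage one of `"average"`, `"complete"`, `"single"`,
#'   `"ward.D2"`.
#' @return list with `row`, `col` ([stats::hclust()] trees) and
#'   `row_order`, `col_order` (leaf orders).
#' @export
hcluster <- function(x, metric = "euclidean", linkage = "average") {
  vals <- if (inherits(x, "intensity_matrix")) x$values else x
  if (!metric %in% c("euclidean", "manhattan", "maximum"))
    stop_arg("unsupported metric '%s'", metric)
  if (!linkage %in% c("average", "complete", "single", "ward.D2"))
    stop_arg("unsupported linkage '%s'", linkage)
  if (anyNA(vals)) stop_arg("missing values present; impute first")
  if (nrow(vals) < 2L) stop_arg("clustering needs >= 2 rows")
  hr <- stats::hclust(stats::dist(vals, method = metric), method = linkage)
  hc <- stats::hclust(stats::dist(t(vals), method = metric),
                      method = linkage)
  list(row = hr, col = hc, row_order = hr$order, col_order = hc$order)
}

#' Principal-component analysis of samples
#'
#' Mean-centered singular-value decomposition with samples as
#' observations. Loadings are orthonormal and the per-component variance
#' explained sums to 100%.
#'
#' @param x an [intensity_matrix()] or numeric proteins x samples matrix
#'   without missing values; >= 2 samples.
#' @param center subtract per-protein means (default `TRUE`).
#' @return list with `scores` (samples x components), `loadings`
#'   (proteins x components, orthonormal) and `variance_explained`
#'   (percent per component).
#' @export
pca_matrix <- function(x, center = TRUE) {
  vals <- if (inherits(x, "intensity_matrix")) x$values else x
  if (anyNA(vals)) stop_arg("missing values present; impute first")
  if (ncol(vals) < 2L) stop_arg("PCA needs >= 2 samples")
  m <- t(vals)                               # samples x proteins
  if (center) m <- sweep(m, 2, colMeans(m))
  sv <- svd(m)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(1L, k)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- colnames(vals)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(vals)
  ve <- 100 * sv$d[seq_len(k)]^2 / sum(sv$d^2)
  colnames(scores) <- colnames(loadings) <- names(ve) <-
    paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings, variance_explained = ve)
}

#' Ranked protein abundance within a group
#'
#' Proteins sorted by descending mean intensity over the samples of one
#' group (missing values ignored), with 1-based ranks; ties rank the
#' lexicographically smaller protein id first. Proteins on a highlight
#' list (e.g. marker candidates) are flagged.
#'
#' @param x an [intensity_matrix()].
#' @param design design table.
#' @param group group whose samples are averaged.
#' @param highlight protein ids to flag; unknown ids warn but do not
#'   error.
#' @return `data.frame` with `protein`, `gene`, `mean_intensity`, `rank`,
#'   `highlight`.
#' @export
rank_abundance <- function(x, design, group, highlight = character()) {
  design <- check_design(x, design, min_per_group = 1L)
  if (!group %in% design$group) stop_arg("group '%s' not in design", group)
  sub <- x$values[, design$sample[design$group == group], drop = FALSE]
  m <- rowMeans(sub, na.rm = TRUE)
  ord <- order(-m, rownames(x$values))
  unknown <- setdiff(highlight, rownames(x$values))
  if (length(unknown))
    warning(sprintf("highlight id(s) not in matrix: %s",
                    paste(unknown, collapse = ", ")))
  data.frame(protein = rownames(x$values)[ord], gene = x$genes[ord],
             mean_intensity = m[ord], rank = seq_along(ord),
             highlight = rownames(x$values)[ord] %in% highlight,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a significant
#' protein set and each user-supplied gene set, relative to a background,
#' with Benjamini-Hochberg adjustment across sets. This is the desk-scale
#' over-representation test used in place of database-backed GO/GSEA
#' enrichment.
#'
#' @param significant character vector, must be a subset of `background`.
#' @param background character vector (the tested universe).
#' @param gene_sets named list of character vectors; each set is
#'   intersected with the background and must be non-empty afterwards
#'   (empty sets are dropped with a warning).
#' @return `data.frame` with `set`, `overlap`, `set_size`, `n_significant`,
#'   `expected`, `fold`, `p_value`, `p_adjust`.
#' @export
ora_hypergeometric <- function(significant, background, gene_sets) {
  significant <- unique(significant); background <- unique(background)
  if (!all(significant %in% background))
    stop_arg("'significant' must be a subset of 'background'")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop_arg("'gene_sets' must be a named list")
  N <- length(background); n <- length(significant)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    if (!length(s)) {
      warning(sprintf("gene set '%s' is empty after intersecting the background; dropped", nm))
      return(NULL)
    }
    k <- length(intersect(significant, s)); K <- length(s)
    expected <- n * K / N
    data.frame(set = nm, overlap = k, set_size = K, n_significant = n,
               expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_arg("no usable gene sets")
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Aggregate replicate samples to patient means
#'
#' Collapses the matrix to one column per patient (mean over that
#' patient's replicates, missing values ignored) to address
#' pseudo-replication when replicates of a patient are not independent
#' units.
#'
#' @param x an [intensity_matrix()].
#' @param design design table with a `patient` column.
#' @return list with the aggregated `matrix` and patient-level `design`.
#' @export
aggregate_by_patient <- function(x, design) {
  design <- check_design(x, design, min_per_group = 1L)
  if (!"patient" %in% names(design)) stop_arg("design lacks 'patient'")
  pats <- unique(design$patient)
  vals <- vapply(pats, function(p)
    rowMeans(x$values[, design$sample[design$patient == p], drop = FALSE],
             na.rm = TRUE), numeric(nrow(x$values)))
  vals[is.nan(vals)] <- NA_real_
  colnames(vals) <- pats
  d2 <- unique(design[, c("patient", "group")])
  list(matrix = intensity_matrix(vals, genes = x$genes, scale = x$scale),
       design = data.frame(sample = d2$patient, group = d2$group,
                           patient = d2$patient, replicate = 1L,
                           stringsAsFactors = FALSE))
}
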