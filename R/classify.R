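#' Classifier configuration
#'
#' Thresholds and scales for the stain-score / morphology nuclei
#' classifier. The stain score separates DAB-brown (CDX2-expressing) from
#' hematoxylin-blue nuclei; the stromal gate additionally requires small
#' area or high eccentricity before a weakly stained nucleus is called
#' stromal rather than unclassified.
#'
#' @param outlier_fraction total fraction removed by the two-tailed
#'   z-scored intensity cut (default 0.05, i.e. 2.5% per tail).
#' @param stain_high threshold at or above which a nucleus is `CDX2++`.
#' @param stain_low threshold at or above which (but below `stain_high`) a
#'   nucleus is `CDX2+`.
#' @param stromal_area_max_um2 stromal gate: maximum nuclear area in
#'   square microns.
#' @param stromal_ecc_min stromal gate: minimum eccentricity.
#' @param um_per_px image scale in microns per pixel.
#' @param lower_pct,upper_pct percentiles mapped to 0 and 1 by
#'   [normalize_rgb()].
#' @return an object of class `"classifier_config"`.
#' @export
classifier_config <- function(outlier_fraction = 0.05, stain_high = 0.25,
                              stain_low = 0.05, stromal_area_max_um2 = 40,
                              stromal_ecc_min = 0.75, um_per_px = 0.5,
                              lower_pct = 1, upper_pct = 99) {
  for (nm in c("outlier_fraction", "stain_high", "stain_low",
               "stromal_area_max_um2", "stromal_ecc_min", "um_per_px")) {
    v <- get(nm)
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_arg("configuration error: '%s' must be a single finite number", nm)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_arg("'outlier_fraction' must lie in [0, 1)")
  if (stain_low >= stain_high)
    stop_arg("'stain_low' must be below 'stain_high'")
  if (um_per_px <= 0) stop_arg("'um_per_px' must be positive")
  structure(list(outlier_fraction = outlier_fraction,
                 stain_high = stain_high, stain_low = stain_low,
                 stromal_area_max_um2 = stromal_area_max_um2,
                 stromal_ecc_min = stromal_ecc_min, um_per_px = um_per_px,
                 lower_pct = lower_pct, upper_pct = upper_pct),
            class = "classifier_config")
}

#' Per-image percentile normalization of RGB channel means
#'
#' For every image and channel, values are rescaled linearly so the
#' `lower_pct` percentile maps to 0 and the `upper_pct` percentile to 1,
#' then clipped to `[0, 1]`. This removes per-slide staining and exposure
#' differences before any cross-image comparison. A constant channel
#' (degenerate scale) normalizes to 0.5 everywhere.
#'
#' @param table nuclei `data.frame` with `image_id`, `mean_r`, `mean_g`,
#'   `mean_b`.
#' @param lower_pct,upper_pct percentiles in `[0, 100]`.
#' @return the table with `norm_r`, `norm_g`, `norm_b` appended.
#' @export
normalize_rgb <- function(table, lower_pct = 1, upper_pct = 99) {
  if (!nrow(table)) {
    table$norm_r <- table$norm_g <- table$norm_b <- numeric(0)
    return(table)
  }
  if (lower_pct >= upper_pct) stop_arg("'lower_pct' must be < 'upper_pct'")
  for (ch in c("r", "g", "b")) table[[paste0("norm_", ch)]] <- NA_real_
  for (img in unique(table$image_id)) {
    rows <- table$image_id == img
    for (ch in c("r", "g", "b")) {
      v <- table[[paste0("mean_", ch)]][rows]
      q <- stats::quantile(v, c(lower_pct, upper_pct) / 100, names = FALSE)
      norm <- if (q[2] - q[1] <= .Machine$double.eps * max(1, abs(q[2]))) {
        rep(0.5, length(v))
      } else {
        pmin(1, pmax(0, (v - q[1]) / (q[2] - q[1])))
      }
      table[[paste0("norm_", ch)]][rows] <- norm
    }
  }
  table
}

#' Remove intensity outliers by a two-tailed z-score cut
#'
#' The summed channel intensity (`mean_r + mean_g + mean_b`) of every
#' nucleus is z-scored within its image; the rows falling in the two
#' symmetric tails (`outlier_fraction / 2` per tail, by empirical
#' z-quantile) are flagged and removed. With zero within-image standard
#' deviation the z-score is undefined and no row is removed (conservative
#' keep).
#'
#' @param table nuclei `data.frame`.
#' @param outlier_fraction total fraction to remove (default 0.05).
#' @return list with elements `kept` and `removed`; both carry a logical
#'   `outlier` column.
#' @export
remove_intensity_outliers <- function(table, outlier_fraction = 0.05) {
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_arg("'outlier_fraction' must lie in [0, 1)")
  table$outlier <- flag_intensity_outliers(table, outlier_fraction)
  list(kept = table[!table$outlier, , drop = FALSE],
       removed = table[table$outlier, , drop = FALSE])
}

flag_intensity_outliers <- function(table, outlier_fraction) {
  out <- logical(nrow(table))
  if (!nrow(table) || outlier_fraction == 0) return(out)
  total <- table$mean_r + table$mean_g + table$mean_b
  for (img in unique(table$image_id)) {
    rows <- which(table$image_id == img)
    s <- stats::sd(total[rows])
    if (!is.finite(s) || s == 0) next  # z undefined: keep everything
    z <- (total[rows] - mean(total[rows])) / s
    cut <- stats::quantile(z, c(outlier_fraction / 2,
                                1 - outlier_fraction / 2), names = FALSE)
    out[rows] <- z < cut[1] | z > cut[2]
  }
  out
}

#' Chromatic stain score of a nucleus
#'
#' `stain_score = (mean_r - mean_b) / (mean_r + mean_b + 1)`: positive for
#' DAB-brown (red-dominant, marker-positive) nuclei, near zero or negative
#' for hematoxylin-blue (marker-negative) nuclei. The +1 in the denominator
#' keeps the score finite for black pixels; the score always lies in
#' (-1, 1).
#'
#' @param table nuclei `data.frame` with `mean_r` and `mean_b`.
#' @return the table with a `stain_score` column appended.
#' @export
#' @examples
#' stain_score(data.frame(mean_r = 165, mean_g = 110, mean_b = 60))$stain_score
stain_score <- function(table) {
  table$stain_score <- (table$mean_r - table$mean_b) /
    (table$mean_r + table$mean_b + 1)
  table
}

#' Classify nuclei into CDX2++ / CDX2+ / CDX2- / unclassified
#'
#' The full classification chain: per-image RGB normalization, stain-score
#' computation, two-tailed intensity-outlier flagging, then the gating
#' rule on non-outliers:
#' \itemize{
#'  \item `stain_score >= stain_high` -> `CDX2++`
#'  \item `stain_low <= stain_score < stain_high` -> `CDX2+`
#'  \item `stain_score < stain_low` and (area below
#'    `stromal_area_max_um2` or eccentricity at or above
#'    `stromal_ecc_min`) -> `CDX2-` (stromal morphology gate)
#'  \item otherwise -> `unclassified`
#' }
#' Intervals are half-open with the lower boundary inclusive, so scores on
#' a threshold go to the higher class. Outlier rows carry `NA` as class.
#'
#' @param table nuclei `data.frame` (raw feature export).
#' @param config a [classifier_config()].
#' @param remove_outliers flag outliers internally (default); set `FALSE`
#'   if the table was already filtered.
#' @return the table augmented with `norm_r/g/b`, `stain_score`,
#'   `area_um2`, `outlier` and `assigned_class`.
#' @export
classify_cells <- function(table, config = classifier_config(),
                           remove_outliers = TRUE) {
  if (!inherits(config, "classifier_config"))
    stop_arg("configuration error: 'config' must be a classifier_config")
  table <- normalize_rgb(table, config$lower_pct, config$upper_pct)
  table <- stain_score(table)
  table$area_um2 <- table$area_px2 * config$um_per_px^2
  table$outlier <- if (remove_outliers)
    flag_intensity_outliers(table, config$outlier_fraction)
  else if ("outlier" %in% names(table)) table$outlier else logical(nrow(table))

  cls <- rep(NA_character_, nrow(table))
  ok <- !table$outlier
  s <- table$stain_score
  stromal <- table$area_um2 < config$stromal_area_max_um2 |
    table$eccentricity >= config$stromal_ecc_min
  cls[ok & s >= config$stain_high] <- "CDX2++"
  cls[ok & s >= config$stain_low & s < config$stain_high] <- "CDX2+"
  cls[ok & s < config$stain_low & stromal] <- "CDX2-"
  cls[ok & is.na(cls)] <- "unclassified"
  table$assigned_class <- cls
  table
}

#' Write a classified nuclei table as CSV
#'
#' The nuclei CSV dialect plus the columns added by [classify_cells()].
#'
#' @param table classified `data.frame`.
#' @param path file path.
#' @export
write_classified_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
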