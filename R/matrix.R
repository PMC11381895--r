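#' Protein-group intensity matrix container
#'
#' A thin S3 wrapper around a numeric proteins x samples matrix, carrying
#' gene symbols and a scale flag. Missing quantifications are `NA`; zeros
#' never encode missingness inside the container (the TSV reader coerces
#' on-disk zeros and blanks to `NA`, the dialect DIA search software
#' emits).
#'
#' @param values numeric matrix, rownames = protein-group ids, colnames =
#'   sample ids.
#' @param genes character vector of gene symbols, one per protein (defaults
#'   to the protein ids).
#' @param scale `"log2"` or `"linear"`.
#' @return an object of class `"intensity_matrix"`.
#' @export
intensity_matrix <- function(values, genes = rownames(values),
                             scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_arg("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_arg("'values' needs protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_arg("duplicate protein ids: %s",
             paste(unique(rownames(values)[duplicated(rownames(values))]),
                   collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_arg("duplicate sample ids: %s",
             paste(unique(colnames(values)[duplicated(colnames(values))]),
                   collapse = ", "))
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop_arg("negative values are not allowed on the linear scale")
  if (length(genes) != nrow(values))
    stop_arg("'genes' must have one entry per protein")
  structure(list(values = values, genes = as.character(genes),
                 scale = scale), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%s scale, %.1f%% missing)\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix by protein and/or sample
#' @param x an [intensity_matrix()].
#' @param i,j protein and sample indices (any matrix-style index).
#' @param ... ignored.
#' @export
`[.intensity_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  ii <- seq_len(nrow(x$values)); names(ii) <- rownames(x$values)
  intensity_matrix(x$values[i, j, drop = FALSE], genes = x$genes[ii[i]],
                   scale = x$scale)
}

#' Convert an intensity matrix between linear and log2 scales
#'
#' @param x an [intensity_matrix()].
#' @return the matrix on the requested scale (a no-op if already there).
#' @export
as_log2 <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale == "log2") return(x)
  intensity_matrix(log2(x$values), genes = x$genes, scale = "log2")
}

#' @rdname as_log2
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$scale == "linear") return(x)
  intensity_matrix(2^x$values, genes = x$genes, scale = "linear")
}

#' Read / write the wide protein-group TSV dialect
#'
#' Tab-separated with columns `Protein.Group`, `Genes`, then one numeric
#' column per sample, as emitted by DIA search software ("pg_matrix").
#' Blanks, `NA` and zeros are read as missing; duplicate protein ids or
#' sample columns are rejected; a non-numeric cell raises an error naming
#' its row and column.
#'
#' @param path TSV file path.
#' @param scale scale flag to attach on read (`"linear"` for raw search
#'   output, `"log2"` for pre-transformed tables).
#' @return `read_matrix` returns an [intensity_matrix()]; `write_matrix`
#'   returns `path` invisibly. Missing values are written as blanks.
#' @export
read_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (!"Protein.Group" %in% names(raw))
    stop_arg("%s: no 'Protein.Group' column", path)
  sample_cols <- names(raw)[!names(raw) %in% c("Protein.Group", "Genes")]
  if (!length(sample_cols)) stop_arg("%s: no sample columns", path)
  if (anyDuplicated(sample_cols))
    stop_arg("%s: duplicate sample column '%s'", path,
             sample_cols[duplicated(sample_cols)][1])
  if (anyDuplicated(raw$Protein.Group))
    stop_arg("%s: duplicate protein id '%s'", path,
             raw$Protein.Group[duplicated(raw$Protein.Group)][1])
  vals <- matrix(NA_real_, nrow(raw), length(sample_cols),
                 dimnames = list(raw$Protein.Group, sample_cols))
  for (j in seq_along(sample_cols)) {
    cell <- trimws(raw[[sample_cols[j]]])
    empty <- cell == "" | cell == "NA" | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop_arg("%s: non-numeric cell '%s' at protein %s, sample %s", path,
               cell[bad[1]], raw$Protein.Group[bad[1]], sample_cols[j])
    num[empty] <- NA_real_
    num[!is.na(num) & num == 0] <- NA_real_  # dialect: 0 means not quantified
    vals[, j] <- num
  }
  genes <- if ("Genes" %in% names(raw)) raw$Genes else raw$Protein.Group
  intensity_matrix(vals, genes = genes, scale = scale)
}

#' @rdname read_matrix
#' @param x an [intensity_matrix()].
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  out <- data.frame(Protein.Group = rownames(x$values), Genes = x$genes,
                    x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample design table (TSV)
#'
#' Columns `sample`, `group`, `patient`, `replicate`; sample ids must be
#' unique.
#'
#' @param design design `data.frame`.
#' @param path TSV file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group")
  if (!all(need %in% names(d)))
    stop_arg("%s: design needs columns %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(d$sample))
    stop_arg("%s: duplicate sample id '%s'", path,
             d$sample[duplicated(d$sample)][1])
  d
}

# design/matrix consistency check used by the statistics layer
check_design <- function(x, design, min_per_group = 2L) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!setequal(design$sample, colnames(x$values)))
    stop_arg("design samples and matrix columns do not match")
  design <- design[match(colnames(x$values), design$sample), , drop = FALSE]
  ng <- table(design$group)
  if (any(ng < min_per_group))
    stop_arg("every group needs >= %d samples (got: %s)", min_per_group,
             paste(sprintf("%s=%d", names(ng), ng), collapse = ", "))
  design
}
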