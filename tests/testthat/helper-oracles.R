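# Independent oracles and tiny fixture builders used across the suite.

# Ray-casting (crossing number, even-odd rule) point-in-polygon oracle,
# written independently of the package's winding-number implementation.
ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check (edge-inclusive convention)
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    if (cr == 0 && px >= min(xi, xj) && px <= max(xi, xj) &&
        py >= min(yi, yj) && py <= max(yi, yj)) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# small complete intensity matrix: each element of group_values holds the
# per-sample values of that group, repeated identically for every protein
toy_matrix <- function(group_values, n_proteins = 3) {
  vals <- do.call(cbind, lapply(group_values, function(v)
    matrix(v, nrow = n_proteins, ncol = length(v), byrow = TRUE)))
  groups <- rep(names(group_values), lengths(group_values))
  colnames(vals) <- sprintf("%s_s%d", groups,
                            sequence(lengths(group_values)))
  rownames(vals) <- sprintf("prot%02d", seq_len(n_proteins))
  list(matrix = intensity_matrix(vals, scale = "log2"),
       design = data.frame(sample = colnames(vals), group = groups,
                           patient = colnames(vals), replicate = 1L,
                           stringsAsFactors = FALSE))
}

# complete random matrix under the global null
null_matrix <- function(n_proteins, design, noise_sd = 0.5, seed) {
  gen_protein_matrix(design, n_proteins, noise_sd = noise_sd,
                     missing = missingness_spec(floor = 0, ceiling = 0),
                     seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
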