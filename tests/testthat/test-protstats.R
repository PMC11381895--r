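test_that("valid-value filter reproduces brute-force enumeration", {
  d <- default_design(n_patients = 1)  # 3 groups x 3 replicates
  # exhaustive grid: all 2^9 presence patterns of one protein
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 9)))
  vals <- matrix(20, nrow(patterns), 9,
                 dimnames = list(sprintf("pat%03d", seq_len(nrow(patterns))),
                                 d$sample))
  vals[!patterns] <- NA
  x <- intensity_matrix(vals, scale = "log2")
  kept <- rownames(filter_valid_values(x, d, min_frac = 0.7)$values)
  # independent oracle: fraction valid within some group >= 0.7
  grp <- split(seq_len(9), d$group[match(colnames(vals), d$sample)])
  oracle <- vapply(seq_len(nrow(patterns)), function(i)
    any(vapply(grp, function(j) mean(patterns[i, j]) >= 0.7, logical(1))),
    logical(1))
  expect_identical(kept, rownames(vals)[oracle])
  # with triplicates the 70% rule demands all three values of some group
  complete_group <- vapply(seq_len(nrow(patterns)), function(i)
    any(vapply(grp, function(j) all(patterns[i, j]), logical(1))),
    logical(1))
  expect_identical(oracle, complete_group)
})

test_that("filter keeps complete matrices, is vacuous at 0 and idempotent", {
  d <- default_design()
  pm <- null_matrix(50, d, seed = 1)
  expect_equal(nrow(filter_valid_values(pm$matrix, d)$values), 50L)
  pm2 <- gen_protein_matrix(d, 200, seed = 2)
  f0 <- filter_valid_values(pm2$matrix, d, min_frac = 0)
  expect_equal(nrow(f0$values), 200L)
  f1 <- filter_valid_values(pm2$matrix, d, min_frac = 0.7)
  f2 <- filter_valid_values(f1, d, min_frac = 0.7)
  expect_identical(f1$values, f2$values)
  expect_error(filter_valid_values(pm2$matrix, d, mode = "everywhere"),
               "unknown filtering mode")
})

test_that("downshifted-normal imputation has the specified moments", {
  # column with observed mean exactly 20 and sd exactly 2
  obs <- scale(rnorm(100))[, 1] * 2 + 20
  vals <- cbind(s1 = c(obs, rep(NA, 10000)),
                s2 = rnorm(10100, 20, 2))
  rownames(vals) <- sprintf("p%05d", seq_len(nrow(vals)))
  x <- intensity_matrix(vals, scale = "log2")
  imp <- impute_mnar(x, seed = 1)
  drawn <- imp$matrix$values[imp$mask[, "s1"], "s1"]
  expect_equal(length(drawn), 10000L)
  expect_lt(abs(mean(drawn) - 17), 3 * 0.6 / sqrt(10000))
  expect_lt(abs(sd(drawn) - 0.6), 3 * 0.6 / sqrt(2 * (10000 - 1)))
  # observed entries untouched
  expect_identical(imp$matrix$values[!imp$mask], vals[!imp$mask])
})

test_that("imputation is deterministic, identity on complete data, and
           refuses starved columns", {
  d <- default_design()
  pm <- gen_protein_matrix(d, 100, seed = 4)
  i1 <- impute_mnar(pm$matrix, seed = 9)
  i2 <- impute_mnar(pm$matrix, seed = 9)
  expect_identical(i1$matrix$values, i2$matrix$values)
  i3 <- impute_mnar(pm$matrix, seed = 10)
  expect_false(identical(i1$matrix$values, i3$matrix$values))

  full <- null_matrix(20, d, seed = 5)
  expect_identical(impute_mnar(full$matrix, seed = 1)$matrix$values,
                   full$matrix$values)

  starved <- intensity_matrix(
    matrix(c(1, NA, NA, 2, 3, 4), 3,
           dimnames = list(c("a", "b", "c"), c("s1", "s2"))),
    scale = "log2")
  expect_error(impute_mnar(starved, seed = 1), "column 's1'")
})

test_that("s0 = 0 recovers the classical pooled t (hand oracle and t.test)", {
  tm <- toy_matrix(list(A = 10:12, B = 14:16))
  # toy triples a = (10,11,12), b = (14,15,16): pooled t = -4.899
  r <- s0_tstat(tm$matrix, tm$design, "A", "B", s0 = 0)
  expect_equal(r$d_stat, rep(-4 / sqrt(2 / 3), 3), tolerance = 1e-9)
  expect_equal(r$d_stat[1], -4.898979, tolerance = 1e-6)
  expect_equal(r$log2_fc, rep(-4, 3))

  set.seed(11)
  vals <- matrix(rnorm(60), 10, dimnames = list(sprintf("p%d", 1:10),
                                                sprintf("s%d", 1:6)))
  des <- data.frame(sample = colnames(vals),
                    group = rep(c("A", "B"), each = 3),
                    patient = colnames(vals), replicate = 1L)
  x <- intensity_matrix(vals, scale = "log2")
  r2 <- s0_tstat(x, des, "A", "B", s0 = 0)
  tt <- apply(vals, 1, function(v)
    t.test(v[1:3], v[4:6], var.equal = TRUE)$statistic)
  expect_equal(r2$d_stat, unname(tt), tolerance = 1e-9)
})

test_that("s0 damps the statistic monotonically and handles zero variance", {
  tm <- toy_matrix(list(A = c(10, 11), B = c(14, 12)))
  d0 <- abs(s0_tstat(tm$matrix, tm$design, "A", "B", s0 = 0)$d_stat)
  d1 <- abs(s0_tstat(tm$matrix, tm$design, "A", "B", s0 = 0.1)$d_stat)
  d2 <- abs(s0_tstat(tm$matrix, tm$design, "A", "B", s0 = 1)$d_stat)
  expect_true(all(d0 > d1 & d1 > d2))
  # equal group means give d = 0
  eq <- toy_matrix(list(A = rep(5, 3), B = rep(5, 3)))
  expect_equal(s0_tstat(eq$matrix, eq$design, "A", "B")$d_stat,
               rep(0, 3))
  # constant data: undefined at s0 = 0, finite at s0 > 0
  expect_warning(r0 <- s0_tstat(eq$matrix, eq$design, "A", "B", s0 = 0),
                 "zero variance")
  expect_true(all(is.na(r0$d_stat)))
})

test_that("s0 = 0 ANOVA equals classical F (hand oracle and aov)", {
  # groups (1,2,3), (2,3,4), (6,7,8): F = 21
  vals <- rbind(g1 = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
  colnames(vals) <- sprintf("s%d", 1:9)
  des <- data.frame(sample = colnames(vals),
                    group = rep(c("A", "B", "C"), each = 3),
                    patient = colnames(vals), replicate = 1L)
  x <- intensity_matrix(vals, scale = "log2")
  r <- anova_s0(x, des, s0 = 0)
  expect_equal(r$d_stat, 21, tolerance = 1e-9)

  set.seed(12)
  vals2 <- matrix(rnorm(90), 10, dimnames = list(sprintf("p%d", 1:10),
                                                 colnames(vals)))
  x2 <- intensity_matrix(vals2, scale = "log2")
  r2 <- anova_s0(x2, des, s0 = 0)
  f_oracle <- apply(vals2, 1, function(v)
    summary(aov(v ~ factor(des$group)))[[1]]$`F value`[1])
  expect_equal(r2$d_stat, unname(f_oracle), tolerance = 1e-9)

  # zero within-group variance, distinct means: finite and large with s0>0
  tm3 <- toy_matrix(list(A = rep(1, 3), B = rep(2, 3), C = rep(6, 3)))
  rz <- anova_s0(tm3$matrix, tm3$design, s0 = 0.1)
  expect_true(all(is.finite(rz$d_stat)) && all(rz$d_stat > 100))
  expect_error(anova_s0(x2, transform(des, group = "A"), s0 = 0.1),
               ">= 2 groups")
})

test_that("permutation FDR: null dominance, monotone q, significance call", {
  # observed contrast balanced to zero while permutations are not
  offs <- c(0, 1, 2, 0, 1, 2)
  vals <- matrix(rep(offs, each = 20), 20, byrow = FALSE) +
    matrix(rnorm(120, 0, 1e-6), 20)
  dimnames(vals) <- list(sprintf("p%d", 1:20), sprintf("s%d", 1:6))
  des <- data.frame(sample = colnames(vals),
                    group = rep(c("A", "B"), each = 3),
                    patient = colnames(vals), replicate = 1L)
  x <- intensity_matrix(vals, scale = "log2")
  r <- permutation_fdr(x, des, "ttest", "A", "B", n_perm = 100, seed = 1)
  expect_true(all(r$q_value >= 0 & r$q_value <= 1))
  expect_equal(sum(r$significant), 0L)
  expect_true(all(r$q_value[order(-abs(r$d_stat))] ==
                    cummin(r$q_value[order(-abs(r$d_stat))])))

  # planted strong effects are recovered
  d <- default_design()
  eff <- effect_spec(sprintf("P%05d", 1:20), "C", 2)
  pm <- gen_protein_matrix(d, 400, effects = eff, noise_sd = 0.5,
                           missing = missingness_spec(floor = 0,
                                                      ceiling = 0),
                           seed = 13)
  rt <- permutation_fdr(pm$matrix, d, "ttest", "C", "NMN", n_perm = 100,
                        q = 0.05, seed = 13)
  planted <- rt$protein %in% eff$protein_id
  expect_gte(mean(rt$significant[planted]), 0.9)
  expect_identical(sign(rt$d_stat), sign(rt$log2_fc))

  ra <- permutation_fdr(pm$matrix, d, "anova", n_perm = 100, q = 0.01,
                        seed = 13)
  expect_gte(mean(ra$significant[ra$protein %in% eff$protein_id]), 0.9)

  tiny <- toy_matrix(list(A = 1, B = 2))
  tiny$design$group <- c("A", "B")
  expect_error(permutation_fdr(tiny$matrix, tiny$design, "ttest",
                               "A", "B", n_perm = 10, seed = 1),
               "exact enumeration|>= 2 samples")
})

test_that("CVs follow 100*sd/mean on valid linear values", {
  vals <- matrix(c(100, 121, NA,  50, 50, 50,  10, NA, NA), 3,
                 byrow = TRUE,
                 dimnames = list(c("pa", "pb", "pc"),
                                 c("g1a", "g1b", "g1c")))
  x <- intensity_matrix(vals, scale = "linear")
  des <- data.frame(sample = colnames(vals), group = "G1",
                    patient = colnames(vals), replicate = 1L)
  cv <- cv_table(x, des)
  expect_equal(unname(cv$cv["pa", "G1"]), 100 * sd(c(100, 121)) / 110.5,
               tolerance = 1e-9)
  expect_equal(unname(cv$cv["pa", "G1"]), 13.43819, tolerance = 1e-5)
  expect_equal(unname(cv$cv["pb", "G1"]), 0)
  expect_true(is.na(cv$cv["pc", "G1"]))
  expect_error(cv_table(as_log2(x), des), "linear scale")
})

test_that("row z-scoring centers and scales; clustering finds structure", {
  set.seed(14)
  vals <- matrix(rnorm(100, 20, 3), 10,
                 dimnames = list(sprintf("p%d", 1:10),
                                 sprintf("s%d", 1:10)))
  z <- zscore_rows(vals)
  expect_lt(max(abs(rowSums(z))), 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 10), tolerance = 1e-9)
  expect_warning(zscore_rows(rbind(vals, flat = rep(1, 10))), "constant")

  # 3 points at mutual distances 1, 1, ~10: close pair merges first
  pts <- matrix(c(0, 0, 1, 0, 10, 0), 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("x", "y")))
  hc <- hcluster(pts, linkage = "average")
  expect_identical(sort(hc$row$merge[1, ]), c(-2L, -1L))
  expect_true(all(diff(hc$row$height) >= 0))
  expect_error(hcluster(pts, metric = "cosine"), "unsupported metric")

  # planted group effects make same-group samples contiguous leaves
  d <- default_design()
  eff <- effect_spec(rep(sprintf("P%05d", 1:30), 2),
                     rep(c("C", "HDA"), each = 30),
                     c(rep(3, 30), rep(-3, 30)))
  pm <- gen_protein_matrix(d, 60, effects = eff, noise_sd = 0.3,
                           missing = missingness_spec(floor = 0,
                                                      ceiling = 0),
                           seed = 15)
  hcp <- hcluster(zscore_rows(pm$matrix$values))
  leaf_groups <- d$group[match(colnames(pm$matrix$values)[hcp$col_order],
                               d$sample)]
  expect_equal(length(rle(leaf_groups)$values), 3L)
})

test_that("PCA: rank-1 data, orthonormal loadings, exact reconstruction", {
  t_line <- outer(c(1, 2, 3), c(1, 1, 2, 3, 5))  # rank-1 proteins x samples
  dimnames(t_line) <- list(c("p1", "p2", "p3"), sprintf("s%d", 1:5))
  p <- pca_matrix(t_line, center = FALSE)
  expect_equal(unname(p$variance_explained[1]), 100, tolerance = 1e-9)

  set.seed(16)
  vals <- matrix(rnorm(120, 20, 2), 20,
                 dimnames = list(sprintf("p%d", 1:20), sprintf("s%d", 1:6)))
  p2 <- pca_matrix(vals)
  gram <- crossprod(p2$loadings)
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(p2$variance_explained), 100, tolerance = 1e-9)
  centered <- sweep(t(vals), 2, colMeans(t(vals)))
  expect_lt(max(abs(p2$scores %*% t(p2$loadings) - centered)), 1e-9)
  expect_error(pca_matrix(vals[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("rank abundance orders, breaks ties lexicographically, flags", {
  vals <- matrix(c(5, 5, 3, 1,  5, 5, 3, 1), 4,
                 dimnames = list(c("zeta", "alpha", "mid", "low"),
                                 c("s1", "s2")))
  des <- data.frame(sample = c("s1", "s2"), group = "G",
                    patient = c("s1", "s2"), replicate = 1L)
  x <- intensity_matrix(vals, scale = "linear")
  r <- rank_abundance(x, des, "G", highlight = "mid")
  expect_identical(r$protein, c("alpha", "zeta", "mid", "low"))
  expect_identical(r$rank, 1:4)
  expect_identical(which(r$highlight), 3L)
  expect_warning(rank_abundance(x, des, "G", highlight = "DMBT1"),
                 "not in matrix")
})

test_that("hypergeometric ORA matches exact enumeration and guards input", {
  bg <- sprintf("g%02d", 1:20)
  sig <- bg[1:5]
  sets <- list(hit = bg[c(1:4, 10, 11)], mixed = bg[c(3, 8, 12, 15)],
               cold = bg[16:20])
  r <- ora_hypergeometric(sig, bg, sets)
  # brute-force hypergeometric mass via binomial coefficients
  exact_p <- function(k, K, N, n)
    sum(vapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
  expect_equal(r$p_value[r$set == "hit"], exact_p(4, 6, 20, 5),
               tolerance = 1e-12)
  expect_equal(r$p_value[r$set == "mixed"], exact_p(1, 4, 20, 5),
               tolerance = 1e-12)
  expect_equal(r$p_adjust, p.adjust(r$p_value, "BH"))

  # a set identical to the significant list in a large background
  bg2 <- sprintf("g%04d", 1:2000)
  r2 <- ora_hypergeometric(bg2[1:20], bg2, list(same = bg2[1:20]))
  expect_lt(r2$p_value, 1e-30)

  expect_error(ora_hypergeometric(c("x", bg[1]), bg, sets), "subset")
  expect_warning(ora_hypergeometric(sig, bg, c(sets, list(none = "zz"))),
                 "dropped")
})

test_that("patient aggregation collapses replicates to patient means", {
  d <- default_design()
  pm <- null_matrix(30, d, seed = 17)
  agg <- aggregate_by_patient(pm$matrix, d)
  expect_equal(ncol(agg$matrix$values), 9L)
  p1 <- d$sample[d$patient == "C_P1"]
  expect_equal(agg$matrix$values[, "C_P1"],
               rowMeans(pm$matrix$values[, p1]), tolerance = 1e-12)
})
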