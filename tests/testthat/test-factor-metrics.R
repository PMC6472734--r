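# decomposition stub with known factor blocks
stub_decomposition <- function(measurement = NULL, participant = NULL,
                               disorder = NULL, n_edges = NULL) {
  blocks <- list(measurement = measurement, participant = participant,
                 disorder = disorder)
  E <- if (!is.null(n_edges)) n_edges else ncol(Filter(Negate(is.null), blocks)[[1]])
  structure(list(measurement = measurement, sampling_hc = NULL,
                 sampling_mdd = NULL, sampling_scz = NULL,
                 disorder = disorder, participant = participant,
                 intercept = rep(0, E), residual_variance = rep(0, E),
                 lambda = 1, n_edges = E),
            class = "bias_decomposition")
}

test_that("magnitude moments match symmetry and scale expectations", {
  half <- matrix(rep(c(0.3, -0.3), each = 50), 1, 100,
                 dimnames = list("S1", NULL))
  mm <- magnitude_moments(stub_decomposition(measurement = half),
                          "measurement")
  expect_equal(mm$per_level$mean, 0)
  expect_equal(mm$per_level$sd, 0.3)
  expect_equal(mm$per_level$third_moment_cuberoot, 0)
  zero <- matrix(0, 2, 10, dimnames = list(c("A", "B"), NULL))
  mz <- magnitude_moments(stub_decomposition(measurement = zero),
                          "measurement")
  expect_true(all(mz$per_level[, -1] == 0))
  # Gaussian SD recovered within sampling error at large edge count
  set.seed(1)
  g <- matrix(rnorm(35778, 0, 0.04), 1, dimnames = list("S1", NULL))
  mg <- magnitude_moments(stub_decomposition(measurement = g), "measurement")
  expect_equal(mg$per_level$sd, 0.04, tolerance = 0.015)
  # SD invariant to a sign flip of the whole vector
  mf <- magnitude_moments(stub_decomposition(measurement = -g), "measurement")
  expect_equal(mf$per_level$sd, mg$per_level$sd)
  expect_error(magnitude_moments(stub_decomposition(measurement = g),
                                 "participant"), "absent")
})

test_that("contribution shares are conserved and scale by level count", {
  study <- tiny_study(n_edges = 30, seed = 21)
  ds <- bind_datasets(study$multisite, study$traveling)
  dec <- fit_all_edges(ds, 1)
  rep <- contribution_sizes(ds, dec)
  expect_lt(max(abs(rep$share_sums - 1)), 1e-8)
  total <- sum(rep$contributions$n_levels * rep$contributions$contribution) +
    rep$noise_share
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("a lone nonzero measurement term contributes 1/N_m", {
  # single multisite subject, single edge, zero residual: the measurement
  # share is 1 and the contribution is 1/12 with 12 sites
  sites <- sprintf("S%02d", 1:12)
  m <- matrix(0, 12, 1, dimnames = list(sites, NULL))
  m[3, 1] <- 0.2
  dec <- stub_decomposition(measurement = m, n_edges = 1)
  meta <- data.frame(row_id = "r1", participant_id = "r1", site_id = "S03",
                     diagnosis = "HC", dataset_kind = "multisite",
                     session_id = "1")
  ds <- fc_dataset(matrix(0.2, 1, 1), meta, build_edge_index(2))
  rep <- contribution_sizes(ds, dec)
  contrib_m <- rep$contributions$contribution[rep$contributions$factor == "m"]
  expect_equal(contrib_m, 1 / 12, tolerance = 1e-12)
  expect_equal(rep$noise_share, 0)
})

test_that("dispersion grid emits one Ansari-Bradley test per pair", {
  set.seed(2)
  p <- matrix(rnorm(9 * 300, 0, 0.06), 9, 300,
              dimnames = list(sprintf("P%d", 1:9), NULL))
  m <- matrix(rnorm(12 * 300, 0, 0.04), 12, 300,
              dimnames = list(sprintf("S%02d", 1:12), NULL))
  dec <- stub_decomposition(measurement = m, participant = p)
  grid <- variance_comparisons(dec, "participant", "measurement")
  expect_equal(nrow(grid), 108)
  expect_true(all(grid$p_bonferroni >= grid$p_value - 1e-15))
  # identical vectors: no dispersion difference
  same <- stub_decomposition(
    measurement = matrix(rnorm(200), 2, 100, byrow = FALSE,
                         dimnames = list(c("A", "B"), NULL)))
  same$measurement["B", ] <- same$measurement["A", ]
  one <- variance_comparisons(same, "measurement", "measurement")
  expect_gt(min(one$p_value[one$level_a == one$level_b]), 0.9)
  # strong scale difference detected after Bonferroni at large N
  big <- stub_decomposition(
    measurement = rbind(A = rnorm(20000), B = 3 * rnorm(20000)))
  res <- variance_comparisons(big, "measurement", "measurement")
  ab <- res[res$level_a == "A" & res$level_b == "B", ]
  expect_lt(ab$p_bonferroni, 0.05)
})

test_that("bias-disorder correlations cover every site x disorder pair", {
  set.seed(3)
  m <- matrix(rnorm(12 * 500), 12, 500, dimnames = list(sprintf("S%02d", 1:12), NULL))
  d <- matrix(rnorm(3 * 500), 3, 500, dimnames = list(c("ASD", "MDD", "SCZ"), NULL))
  d["MDD", ] <- m["S01", ]  # a perfectly matching pair
  dec <- stub_decomposition(measurement = m, disorder = d)
  res <- bias_disorder_correlation(dec)
  expect_equal(dim(res$correlations), c(12L, 3L))
  expect_equal(res$t_test$parameter[["df"]], 35)
  expect_equal(res$correlations["S01", "MDD"], 1)
  # orthogonal random vectors: small mean correlation
  expect_lt(mean(abs(res$correlations[-1, ])), 0.15)
})

test_that("ROI projection averages incident edges and commutes with relabeling", {
  idx <- build_edge_index(3)
  m <- matrix(c(2, 4, 6), 1, 3, dimnames = list("S1", NULL))  # e21, e31, e32
  dec <- stub_decomposition(measurement = m)
  map <- roi_projection(dec, "measurement", idx)
  expect_equal(map$roi_effect, c((2 + 4) / 2, (2 + 6) / 2, (4 + 6) / 2))
  # uniform effects: flat map, z-scores undefined-free via all equal
  mu <- matrix(1, 1, 3, dimnames = list("S1", NULL))
  expect_equal(roi_projection(stub_decomposition(measurement = mu),
                              "measurement", idx)$roi_effect, rep(1, 3))
  # relabeling nodes permutes the map identically
  perm <- c(2L, 3L, 1L)  # node k -> perm[k]
  idx_p <- idx
  i2 <- perm[idx$i]; j2 <- perm[idx$j]
  idx_p$i <- pmax(i2, j2); idx_p$j <- pmin(i2, j2)
  map_p <- roi_projection(dec, "measurement", idx_p)
  expect_equal(map_p$roi_effect[perm], map$roi_effect)
  # effects concentrated on one node rank it top
  conc <- matrix(c(5, 5, 0.1), 1, 3, dimnames = list("S1", NULL))
  mc <- roi_projection(stub_decomposition(measurement = conc),
                       "measurement", idx)
  expect_equal(which.max(mc$roi_effect), 1L)
})

test_that("measurement-bias clustering uses 1 - r heights and recovers groups", {
  set.seed(4)
  a <- rnorm(400)
  dup <- rbind(A = a, B = a, C = rnorm(400))
  dec <- stub_decomposition(measurement = dup)
  dend <- cluster_measurement_bias(dec)
  expect_lt(dend$hclust$height[1], 1e-10)  # identical vectors merge at 0
  expect_true(all(dend$hclust$height >= -1e-12 & dend$hclust$height <= 2))
  anti <- rbind(A = a, B = -a)
  expect_equal(cluster_measurement_bias(
    stub_decomposition(measurement = anti))$distance["A", "B"], 2)
  expect_error(cluster_measurement_bias(
    stub_decomposition(measurement = rbind(A = rep(1, 5), B = rnorm(5)))),
    "constant")
  # 12 sites with nested group offsets: 2-cluster cut recovers the top split
  shared <- matrix(rnorm(12 * 600, 0, 0.2), 12, 600)
  pe <- rep(c(-1, 1), each = 6)   # top-level grouping (opposite-sign offsets)
  man <- rep(c(0, 0.3, 0.6, 0, 0.3, 0.6), each = 2)
  signal_dir <- rnorm(600)
  biases <- shared + outer(pe, signal_dir) + outer(man, rnorm(600) * 0.5)
  rownames(biases) <- sprintf("S%02d", 1:12)
  cut <- cutree(cluster_measurement_bias(
    stub_decomposition(measurement = biases))$hclust, k = 2)
  expect_equal(length(unique(cut[pe == -1])), 1L)
  expect_equal(length(unique(cut[pe == 1])), 1L)
  expect_false(cut[1] == cut[12])
})

test_that("per-edge site ANOVA matches lm and calibrates under the null", {
  set.seed(5)
  meta <- data.frame(row_id = sprintf("r%03d", 1:60),
                     participant_id = sprintf("r%03d", 1:60),
                     site_id = rep(c("A", "B", "C"), each = 20),
                     diagnosis = "HC", dataset_kind = "multisite",
                     session_id = "1")
  idx <- build_edge_index(21)
  vals <- matrix(rnorm(60 * 210), 60, 210)
  ds <- fc_dataset(vals, meta, idx)
  res <- site_effect_anova(ds)
  # oracle: classical one-way ANOVA via lm on sampled edges
  for (e in c(1, 57, 210)) {
    or <- anova(lm(vals[, e] ~ meta$site_id))
    expect_equal(unname(res$F[e]), or$`F value`[1], tolerance = 1e-10)
    expect_equal(unname(res$p_value[e]), or$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_lt(res$significant_fraction, 0.02)  # null: nothing survives Bonferroni
  # large injected site offsets: everything significant
  vals2 <- vals + outer(rep(c(0, 2, 4), each = 20), rep(1, 210))
  res2 <- site_effect_anova(fc_dataset(vals2, meta, idx))
  expect_equal(res2$significant_fraction, 1)
  # exactly equal group means at an edge: F = 0
  vals3 <- vals
  vals3[, 1] <- rep(c(-1, 1), 30)
  res3 <- site_effect_anova(fc_dataset(vals3, meta, idx))
  expect_lt(res3$F[1], 1e-20)
})
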