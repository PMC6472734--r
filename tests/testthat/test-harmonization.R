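test_that("traveling-subject harmonization removes only the measurement bias", {
  params <- reference_scale_params()
  params$noise_sd <- 0
  params$xi <- 0
  study <- tiny_study(n_edges = 20, seed = 41, params = params)
  combined <- bind_datasets(study$multisite, study$traveling)
  model <- fit_traveling_subject(combined, lambda = 1e-8)
  harmonized <- apply_harmonization(combined, model)
  refit <- fit_all_edges(harmonized, lambda = 1e-8)
  expect_lt(max(abs(refit$measurement)), 1e-6)
  # sampling-bias structure untouched
  before <- fit_all_edges(combined, lambda = 1e-8)$sampling_hc
  expect_equal(refit$sampling_hc, before, tolerance = 1e-6)
})

test_that("traveling-subject apply is a plain per-site subtraction", {
  study <- tiny_study(n_edges = 10, seed = 42)
  combined <- bind_datasets(study$multisite, study$traveling)
  model <- fit_traveling_subject(combined, lambda = 1)
  once <- apply_harmonization(combined, model)
  twice <- apply_harmonization(once, model)
  shift <- model$site_terms[combined$meta$site_id, , drop = FALSE]
  expect_equal(twice$values, combined$values - 2 * shift, tolerance = 1e-12)
})

test_that("traveling-subject model refuses uncovered sites", {
  study <- tiny_study(n_edges = 10, seed = 43)
  tr <- subset_rows(study$traveling, study$traveling$meta$site_id != "ST04")
  expect_error(fit_traveling_subject(bind_datasets(study$multisite, tr)),
               "ST04")
})

test_that("GLM harmonization equalizes per-site means exactly", {
  set.seed(44)
  idx <- build_edge_index(3)
  meta <- data.frame(row_id = sprintf("r%02d", 1:20),
                     participant_id = sprintf("r%02d", 1:20),
                     site_id = rep(c("A", "B"), each = 10),
                     diagnosis = "HC", dataset_kind = "multisite",
                     session_id = "1")
  vals <- matrix(rnorm(20 * 3), 20, 3)
  vals[1:10, 1] <- vals[1:10, 1] - mean(vals[1:10, 1]) + 1
  vals[11:20, 1] <- vals[11:20, 1] - mean(vals[11:20, 1]) + 3
  ds <- fc_dataset(vals, meta, idx)
  model <- fit_glm(ds)
  harm <- apply_harmonization(ds, model)
  ma <- colMeans(harm$values[1:10, ])
  mb <- colMeans(harm$values[11:20, ])
  expect_equal(ma, mb, tolerance = 1e-10)
  expect_equal(unname(ma[1]), 2, tolerance = 1e-10)  # grand mean preserved
  # single-site data are an error
  expect_error(fit_glm(subset_rows(ds, 1:10)), "2 sites")
})

test_that("GLM removes disorder signal confounded with site", {
  # one site is all-MDD: its site term soaks up the disorder effect
  set.seed(45)
  idx <- build_edge_index(3)
  n <- 30
  meta <- data.frame(row_id = sprintf("r%02d", 1:n),
                     participant_id = sprintf("r%02d", 1:n),
                     site_id = rep(c("A", "B"), each = 15),
                     diagnosis = rep(c("HC", "MDD"), each = 15),
                     dataset_kind = "multisite", session_id = "1")
  d_effect <- c(0.5, -0.4, 0.3)
  vals <- matrix(rnorm(n * 3, 0, 0.05), n, 3)
  vals[16:30, ] <- sweep(vals[16:30, ], 2, d_effect, "+")
  ds <- fc_dataset(vals, meta, idx)
  harm_glm <- apply_harmonization(ds, fit_glm(ds))
  post_d <- colMeans(harm_glm$values[16:30, ]) -
    colMeans(harm_glm$values[1:15, ])
  expect_lt(max(abs(post_d)), 0.1)  # disorder contrast destroyed
})

test_that("adjusted GLM recovers site terms and preserves disorder contrasts", {
  # balanced design: both diagnoses at both sites, additive effects
  set.seed(46)
  idx <- build_edge_index(3)
  n <- 40
  site <- rep(c("A", "B"), each = 20)
  diagnosis <- rep(rep(c("HC", "MDD"), each = 10), 2)
  site_effect <- ifelse(site == "A", 0.3, -0.3)
  d_effect <- c(0.5, -0.4, 0.3)
  vals <- matrix(rnorm(n * 3, 0, 0.02), n, 3) + site_effect
  vals[diagnosis == "MDD", ] <- sweep(vals[diagnosis == "MDD", ], 2,
                                      d_effect, "+")
  meta <- data.frame(row_id = sprintf("r%02d", 1:n),
                     participant_id = sprintf("r%02d", 1:n),
                     site_id = site, diagnosis = diagnosis,
                     dataset_kind = "multisite", session_id = "1")
  ds <- fc_dataset(vals, meta, idx)
  model <- fit_adjusted_glm(ds)
  expect_equal(unname(model$site_terms["A", ]), rep(0.3, 3), tolerance = 0.02)
  expect_equal(unname(model$covariate_terms["MDD", ]), d_effect,
               tolerance = 0.02)
  harm <- apply_harmonization(ds, model)
  post_d <- colMeans(harm$values[diagnosis == "MDD", ]) -
    colMeans(harm$values[diagnosis == "HC", ])
  expect_equal(unname(post_d), d_effect, tolerance = 0.02)
  # no diagnosis variation: reduces to the GLM fit
  hc_only <- subset_rows(ds, diagnosis == "HC")
  expect_equal(fit_adjusted_glm(hc_only)$site_terms,
               fit_glm(hc_only)$site_terms, tolerance = 1e-10)
})

test_that("in-package ComBat matches the reference implementation", {
  skip_if_not_installed("sva")
  study <- tiny_study(n_edges = 50, seed = 47)
  ms <- study$multisite
  ours <- apply_harmonization(ms, fit_combat(ms))$values
  mod <- stats::model.matrix(~ factor(ms$meta$diagnosis))
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(ms$values), batch = ms$meta$site_id, mod = mod)))
  expect_lt(max(abs(ours - ref)), 1e-6)
})

test_that("ComBat aligns site means and variances at large n", {
  set.seed(48)
  idx <- build_edge_index(5)
  n <- 4000
  E <- 10
  site <- rep(c("A", "B"), each = n / 2)
  # heterogeneous per-edge location and scale effects, so the EB priors are
  # broad and the posterior is data-dominated at this sample size
  mult <- runif(E, 0.7, 2.5)
  shift <- rnorm(E, 0.6, 0.5)
  vals <- matrix(rnorm(n * E), n, E)
  vals[site == "B", ] <- sweep(sweep(vals[site == "B", ], 2, mult, "*"),
                               2, shift, "+")
  meta <- data.frame(row_id = sprintf("r%05d", 1:n),
                     participant_id = sprintf("r%05d", 1:n),
                     site_id = site, diagnosis = "HC",
                     dataset_kind = "multisite", session_id = "1")
  ds <- fc_dataset(vals, meta, idx)
  model <- fit_combat(ds)
  expect_true(all(model$scale_terms > 0))
  harm <- apply_harmonization(ds, model)
  mA <- colMeans(harm$values[site == "A", ])
  mB <- colMeans(harm$values[site == "B", ])
  vA <- apply(harm$values[site == "A", ], 2, var)
  vB <- apply(harm$values[site == "B", ], 2, var)
  expect_lt(max(abs(mA - mB)), 0.02 * sd(vals))
  expect_lt(max(abs(vA / vB - 1)), 0.05)
  # non-ComBat additive methods leave the variance differences intact
  harm_glm <- apply_harmonization(ds, fit_glm(ds))
  vB_glm <- apply(harm_glm$values[site == "B", ], 2, var)
  vA_glm <- apply(harm_glm$values[site == "A", ], 2, var)
  raw_ratio <- apply(vals[site == "B", ], 2, var) /
    apply(vals[site == "A", ], 2, var)
  expect_equal(unname(vB_glm / vA_glm), unname(raw_ratio), tolerance = 1e-10)
  expect_gt(max(abs(vB_glm / vA_glm - 1)), 0.5)
})

test_that("ComBat degenerate cases stay finite", {
  # single edge, identical sites: near-zero shift, near-unit scale
  set.seed(49)
  idx <- build_edge_index(2)
  n <- 40
  meta <- data.frame(row_id = sprintf("r%02d", 1:n),
                     participant_id = sprintf("r%02d", 1:n),
                     site_id = rep(c("A", "B"), each = n / 2),
                     diagnosis = "HC", dataset_kind = "multisite",
                     session_id = "1")
  x <- rnorm(n)
  ds <- fc_dataset(matrix(x, n, 1), meta, idx)
  model <- fit_combat(ds)
  expect_lt(max(abs(model$site_terms)), 0.5)
  expect_true(all(model$scale_terms > 0))
})

test_that("apply_harmonization is identity for a zero model", {
  study <- tiny_study(n_edges = 10, seed = 50)
  ms <- study$multisite
  model <- fit_glm(ms)
  model$site_terms[] <- 0
  out <- apply_harmonization(ms, model)
  expect_equal(out$values, ms$values)
  # unknown sites error by default, pass through with "zero"
  model2 <- fit_glm(ms)
  rownames(model2$site_terms)[1] <- "NOPE"
  expect_error(apply_harmonization(ms, model2), "not in model")
  out2 <- apply_harmonization(ms, model2, unknown_sites = "zero")
  orphan <- ms$meta$site_id == sort(unique(ms$meta$site_id))[1]
  expect_equal(out2$values[orphan, ], ms$values[orphan, ])
})
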