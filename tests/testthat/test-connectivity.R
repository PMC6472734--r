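test_that("framewise displacement follows the Power convention", {
  motion <- matrix(0, 5, 6)
  expect_equal(compute_fd(motion), rep(0, 5))
  motion[3, 1] <- 1  # 1 mm translation step (and back)
  fd <- compute_fd(motion)
  expect_equal(fd[3], 1.0)
  expect_equal(fd[4], 1.0)
  motion2 <- matrix(0, 3, 6)
  motion2[2, 4] <- 0.02  # rad, radius 50 mm -> 1.0 mm arc
  expect_equal(compute_fd(motion2, head_radius_mm = 50)[2], 1.0)
  expect_error(compute_fd(matrix(NA_real_, 3, 6)), "non-finite")
})

test_that("scrubbing removes exactly the above-threshold volumes", {
  s <- scrub_volumes(c(0, 0.2, 0.7, 0.3, 0.51), 0.5)
  expect_equal(which(!s$keep), c(3L, 5L))
  expect_equal(s$n_removed, 2L)
  expect_equal(scrub_volumes(c(0.1, 0.2), 0.5)$n_removed, 0L)
  expect_error(scrub_volumes(c(0.1), 0), "positive")
})

test_that("scrubbed fraction tracks the exceedance probability", {
  set.seed(42)
  fd <- abs(rnorm(20000, 0.25, 0.16))
  expected <- mean(fd > 0.5)
  expect_equal(scrub_volumes(fd, 0.5)$n_removed / length(fd), expected)
  expect_gt(expected, 0.03)  # regime comparable to real scrub rates
  expect_lt(expected, 0.12)
})

test_that("nuisance design has 36 columns with correct derivatives", {
  T_ <- 60
  motion <- matrix(rnorm(T_ * 6), T_, 6)
  d <- build_nuisance_design(motion, rnorm(T_), rnorm(T_), rnorm(T_))
  expect_equal(ncol(d), 36L)
  # constant inputs: derivative columns all zero
  dc <- build_nuisance_design(matrix(1, T_, 6), rep(2, T_), rep(3, T_),
                              rep(4, T_))
  expect_true(all(dc[, grep("^d_", colnames(dc))] == 0))
  # linear motion: derivative constant 1 (after zero first row), square = t^2
  motion_lin <- matrix(0, T_, 6)
  motion_lin[, 1] <- seq_len(T_)
  dl <- build_nuisance_design(motion_lin, rnorm(T_), rnorm(T_), rnorm(T_))
  expect_equal(dl[-1, "d_motion1"], rep(1, T_ - 1))
  expect_equal(dl[, "sq_motion1"], (seq_len(T_))^2)
})

test_that("nuisance regression matches the normal-equations oracle", {
  set.seed(3)
  T_ <- 80
  design <- matrix(rnorm(T_ * 5), T_, 5)
  y <- matrix(rnorm(T_ * 3), T_, 3)
  res <- regress_nuisance(y, design)
  X <- cbind(1, design)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(res, oracle, tolerance = 1e-10)
  # residuals orthogonal to regressors
  expect_lt(max(abs(cor(res, design))), 1e-8)
  # signal inside the design space is annihilated
  res2 <- regress_nuisance(2 * design[, 1, drop = FALSE], design)
  expect_lt(max(abs(res2)), 1e-10)
})

test_that("band-pass removes DC and attenuates out-of-band frequencies", {
  tr <- 2.5
  t <- (0:399) * tr
  expect_lt(max(abs(bandpass_filter(rep(5, 400), tr))), 1e-6)
  in_band <- sin(2 * pi * 0.03 * t)
  out_band <- sin(2 * pi * 0.18 * t)
  g_in <- sine_amplitude(bandpass_filter(in_band, tr), 0.03, tr)
  g_out <- sine_amplitude(bandpass_filter(out_band, tr), 0.18, tr)
  expect_gt(g_in, 0.8)
  expect_lt(g_out, 0.35)
  # zero-phase double application squares the gain at each frequency
  twice <- sine_amplitude(bandpass_filter(bandpass_filter(in_band, tr), tr),
                          0.03, tr)
  expect_equal(twice, g_in^2, tolerance = 0.05)
  expect_error(bandpass_filter(in_band, tr, 0.01, 0.3), "Nyquist")
})

test_that("connectivity is Fisher-z of Pearson correlation", {
  idx <- build_edge_index(3)
  set.seed(4)
  n <- 4000
  base <- rnorm(n)
  # construct a pair with population correlation 0.5
  y2 <- 0.5 * base + sqrt(1 - 0.25) * rnorm(n)
  series <- cbind(base, y2, rnorm(n))
  out <- compute_connectivity(series, idx)
  expect_equal(out$z[1], atanh(cor(base, y2)))
  expect_equal(out$z[1], 0.5493, tolerance = 0.06)
  expect_lt(abs(out$z[2]), 0.05)  # independent channels
  # identical series: capped, finite
  dup <- cbind(base, base, rnorm(n))
  expect_true(is.finite(compute_connectivity(dup, idx)$z[1]))
  # zero-variance ROI flagged
  flat <- cbind(base, rep(1, n), rnorm(n))
  expect_equal(compute_connectivity(flat, idx)$flagged_rois, 2L)
})

test_that("exclusion check flags outlying scrub counts", {
  expect_length(exclusion_check(c(a = 5, b = 5, c = 5)), 0)
  counts <- c(rep(10, 20), 200)
  names(counts) <- sprintf("s%02d", 1:21)
  expect_equal(exclusion_check(counts), "s21")
  set.seed(9)
  gauss <- rnorm(1000, 50, 5)
  frac <- length(exclusion_check(gauss)) / 1000
  expect_lt(frac, 0.01)  # ~0.13% expected for a 3 SD tail
})

test_that("pipeline recovers stronger coupling with stronger latent source", {
  # AR(1) source shared by two of ten ROIs (few enough that global-signal
  # regression does not absorb the source itself)
  idx <- build_edge_index(10)
  z_at <- function(strength, seed) {
    set.seed(seed)
    T_ <- 300
    src <- as.numeric(stats::filter(rnorm(T_), 0.5, method = "recursive"))
    series <- sapply(1:10, function(k) {
      (if (k <= 2) strength * src else 0) + rnorm(T_)
    })
    motion <- cbind(matrix(rnorm(T_ * 3, 0, 0.01), T_, 3),
                    matrix(rnorm(T_ * 3, 0, 1e-4), T_, 3))
    connectivity_pipeline(series, motion, idx, tr_seconds = 2.5)$z[1]
  }
  zs <- sapply(c(0, 0.7, 2), z_at, seed = 11)
  expect_true(all(diff(zs) > 0))
})
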