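# Summaries of fitted biases and factors: magnitude-distribution moments,
# contribution sizes, dispersion tests, bias-disorder pattern correlations,
# ROI projection, hierarchical clustering and per-edge site ANOVA.

factor_block <- function(decomposition, factor) {
  block <- decomposition[[factor]]
  if (is.null(block)) {
    stop("factor '", factor, "' absent from the decomposition", call. = FALSE)
  }
  block
}

#' Moments of the magnitude distribution of a factor
#'
#' Per level (site or participant): mean, population standard deviation,
#' and the signed cube root of the third central moment of the edge-wise
#' value distribution; the factor-level summary is the mean and SD of each
#' statistic across levels.
#'
#' @param decomposition A `bias_decomposition`.
#' @param factor One of `"measurement"`, `"sampling_hc"`, `"sampling_mdd"`,
#'   `"sampling_scz"`, `"disorder"`, `"participant"`.
#' @return List of class `magnitude_summary`: `per_level` data.frame
#'   (`level`, `mean`, `sd`, `third_moment_cuberoot`) and `summary`
#'   data.frame (mean and SD of each statistic across levels).
#' @export
magnitude_moments <- function(decomposition, factor) {
  block <- factor_block(decomposition, factor)
  if (nrow(block) == 0) stop("factor '", factor, "' is empty", call. = FALSE)
  mu <- rowMeans(block)
  centered <- block - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  m3 <- rowMeans(centered^3)
  cuberoot <- sign(m3) * abs(m3)^(1 / 3)
  per_level <- data.frame(level = rownames(block), mean = mu, sd = sd_pop,
                          third_moment_cuberoot = cuberoot,
                          row.names = NULL, stringsAsFactors = FALSE)
  summary <- data.frame(
    statistic = c("mean", "sd", "third_moment_cuberoot"),
    across_level_mean = c(mean(mu), mean(sd_pop), mean(cuberoot)),
    across_level_sd = c(stats::sd(mu), stats::sd(sd_pop), stats::sd(cuberoot)))
  structure(list(factor = factor, per_level = per_level, summary = summary),
            class = "magnitude_summary")
}

# per-row factor term values (rows x edges) for each model term
row_terms <- function(dataset, decomposition) {
  meta <- dataset$meta
  n <- nrow(meta)
  E <- decomposition$n_edges
  zero <- matrix(0, n, E)
  term_for <- function(block, keys) {
    if (is.null(block)) return(zero)
    out <- zero
    hit <- keys %in% rownames(block)
    out[hit, ] <- block[keys[hit], , drop = FALSE]
    out
  }
  multi <- meta$dataset_kind == "multisite"
  trav <- meta$dataset_kind == "traveling"
  keys_if <- function(cond, keys) ifelse(cond, keys, NA_character_)
  list(
    m = term_for(decomposition$measurement, meta$site_id),
    s_hc = term_for(decomposition$sampling_hc,
                    keys_if(multi & meta$diagnosis == "HC", meta$site_id)),
    s_mdd = term_for(decomposition$sampling_mdd,
                     keys_if(multi & meta$diagnosis == "MDD", meta$site_id)),
    s_scz = term_for(decomposition$sampling_scz,
                     keys_if(multi & meta$diagnosis == "SCZ", meta$site_id)),
    d = term_for(decomposition$disorder,
                 keys_if(multi, meta$diagnosis)),
    p = term_for(decomposition$participant,
                 keys_if(trav, meta$participant_id))
  )
}

#' Contribution size of each bias and factor
#'
#' For every (subject, edge) cell, the squared value of each fitted model
#' term is divided by the sum of all squared terms plus the squared
#' residual, giving shares that sum to one. The contribution size of a
#' factor is the average share over subjects and edges divided by the
#' factor's level count; the residual's average share is reported as the
#' noise share, so that `sum(N_f * contribution_f) + noise == 1`.
#'
#' @param dataset The `fc_dataset` the decomposition was fitted on.
#' @param decomposition A `bias_decomposition`.
#' @return List of class `contribution_report`: `contributions` data.frame
#'   (`factor`, `n_levels`, `contribution`), `noise_share`, and
#'   `share_sums` (per-cell share totals; all 1 unless a degenerate
#'   all-zero cell occurred).
#' @export
contribution_sizes <- function(dataset, decomposition) {
  terms <- row_terms(dataset, decomposition)
  fitted <- Reduce(`+`, terms)
  resid <- sweep(dataset$values, 2, decomposition$intercept, "-") - fitted
  sq <- lapply(terms, function(t) t^2)
  denom <- Reduce(`+`, sq) + resid^2
  degenerate <- denom == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " (subject, edge) cells have all-zero terms; shares set to 0",
            call. = FALSE)
    denom[degenerate] <- 1
  }
  n_cells <- length(denom)
  shares <- vapply(sq, function(s) sum(s / denom) / n_cells, numeric(1))
  noise <- sum(resid^2 / denom) / n_cells
  n_levels <- c(
    m = nlevels_of(decomposition$measurement),
    s_hc = nlevels_of(decomposition$sampling_hc),
    s_mdd = nlevels_of(decomposition$sampling_mdd),
    s_scz = nlevels_of(decomposition$sampling_scz),
    d = nlevels_of(decomposition$disorder),
    p = nlevels_of(decomposition$participant))
  keep <- n_levels > 0
  contributions <- data.frame(
    factor = names(shares)[keep],
    n_levels = as.integer(n_levels[keep]),
    contribution = shares[keep] / n_levels[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  share_sums <- (Reduce(`+`, sq) + resid^2) / denom
  share_sums[degenerate] <- 0
  structure(list(contributions = contributions, noise_share = noise,
                 share_sums = share_sums),
            class = "contribution_report")
}

nlevels_of <- function(block) if (is.null(block)) 0L else nrow(block)

#' Pairwise dispersion tests between two factors' magnitude distributions
#'
#' Ansari-Bradley test for every (level of `factor_a`) x (level of
#' `factor_b`) pair -- 9 participants x 12 sites = 108 pairs in the
#' reference design -- with Bonferroni correction over the grid.
#'
#' @param decomposition A `bias_decomposition`.
#' @param factor_a,factor_b Factor names as in [magnitude_moments()].
#' @param exact Passed to [stats::ansari.test()] (default FALSE: normal
#'   approximation, as appropriate for edge counts in the tens of
#'   thousands).
#' @return Data.frame with `level_a`, `level_b`, `statistic`, `p_value`,
#'   `p_bonferroni`.
#' @export
variance_comparisons <- function(decomposition, factor_a = "participant",
                                 factor_b = "measurement", exact = FALSE) {
  a <- factor_block(decomposition, factor_a)
  b <- factor_block(decomposition, factor_b)
  if (ncol(a) != ncol(b)) stop("factor vectors have unequal length", call. = FALSE)
  grid <- expand.grid(level_a = rownames(a), level_b = rownames(b),
                      stringsAsFactors = FALSE)
  res <- t(vapply(seq_len(nrow(grid)), function(r) {
    ht <- stats::ansari.test(a[grid$level_a[r], ], b[grid$level_b[r], ],
                             exact = exact)
    c(ht$statistic, ht$p.value)
  }, numeric(2)))
  out <- data.frame(grid, statistic = res[, 1], p_value = res[, 2],
                    stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' Correlations between measurement biases and disorder factors
#'
#' Pearson correlation of every site's measurement-bias vector with every
#' disorder factor (12 x 3 = 36 pairs in the reference design), plus a
#' one-sample t test of the absolute correlations against zero with
#' `df = pairs - 1`.
#'
#' @param decomposition A `bias_decomposition`.
#' @return List of class `bias_disorder_correlation`: `correlations`
#'   (site x disorder matrix; `NA` with a warning for constant vectors),
#'   `t_test` (htest on `abs(r)`), `mean_abs`, `max_abs`.
#' @export
bias_disorder_correlation <- function(decomposition) {
  m <- factor_block(decomposition, "measurement")
  d <- factor_block(decomposition, "disorder")
  const_m <- apply(m, 1, stats::sd) == 0
  const_d <- apply(d, 1, stats::sd) == 0
  if (any(const_m) || any(const_d)) {
    warning("constant vectors (correlation undefined): ",
            paste(c(rownames(m)[const_m], rownames(d)[const_d]),
                  collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(m), t(d)))
  abs_r <- abs(r[is.finite(r)])
  tt <- stats::t.test(abs_r, mu = 0)
  structure(list(correlations = r, t_test = tt,
                 mean_abs = mean(abs_r), max_abs = max(abs_r)),
            class = "bias_disorder_correlation")
}

#' Project per-edge factor effects onto ROIs
#'
#' The effect of a bias on an edge is the median absolute value across
#' levels (sites or participants); for a disorder factor it is the
#' absolute value of that factor's edge vector. The effect on ROI n is the
#' mean effect over all edges incident to n, optionally z-scored across
#' ROIs.
#'
#' @param decomposition A `bias_decomposition`.
#' @param factor Factor name; for `"disorder"`, `level` selects the
#'   diagnosis.
#' @param edge_index The `edge_index` of the fitted data.
#' @param level Disorder level (e.g. `"MDD"`) when `factor = "disorder"`.
#' @param z_score If `TRUE`, z-score the ROI map.
#' @return List of class `roi_effect_map`: `roi_effect` (length
#'   `n_nodes`), `edge_effect`, `factor`.
#' @export
roi_projection <- function(decomposition, factor, edge_index, level = NULL,
                           z_score = FALSE) {
  block <- factor_block(decomposition, factor)
  edge_effect <- if (factor == "disorder") {
    if (is.null(level)) stop("'level' required for disorder factor", call. = FALSE)
    abs(block[level, ])
  } else {
    apply(abs(block), 2, stats::median)
  }
  if (length(edge_effect) != edge_index$n_edges) {
    stop("edge_index inconsistent with decomposition", call. = FALSE)
  }
  K <- edge_index$n_nodes
  sums <- numeric(K)
  counts <- numeric(K)
  for (node in list(edge_index$i, edge_index$j)) {
    t1 <- tapply(edge_effect, node, sum)
    sums[as.integer(names(t1))] <- sums[as.integer(names(t1))] + t1
    t2 <- tapply(rep(1, length(node)), node, sum)
    counts[as.integer(names(t2))] <- counts[as.integer(names(t2))] + t2
  }
  roi <- sums / counts
  if (z_score) roi <- (roi - mean(roi)) / stats::sd(roi)
  structure(list(roi_effect = roi, edge_effect = edge_effect,
                 factor = factor, level = level),
            class = "roi_effect_map")
}

#' Hierarchical clustering of measurement-bias patterns
#'
#' Pairwise distance `1 - r` between the sites' measurement-bias vectors,
#' clustered with [stats::hclust()]. Merge heights lie in [0, 2].
#'
#' @param decomposition A `bias_decomposition`.
#' @param linkage_method Linkage criterion for `hclust` (default
#'   `"average"`).
#' @return List of class `bias_dendrogram`: `hclust` (the tree),
#'   `distance` (site x site matrix of `1 - r`), `correlation`.
#' @export
cluster_measurement_bias <- function(decomposition, linkage_method = "average") {
  m <- factor_block(decomposition, "measurement")
  if (nrow(m) < 2) stop("need at least 2 sites", call. = FALSE)
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    stop("constant measurement-bias vector at site(s): ",
         paste(rownames(m)[const], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(m))
  d <- 1 - r
  tree <- stats::hclust(stats::as.dist(d), method = linkage_method)
  structure(list(hclust = tree, distance = d, correlation = r),
            class = "bias_dendrogram")
}

#' Per-edge one-way site ANOVA
#'
#' F test of site differences at every edge of a multisite dataset, with
#' the Bonferroni threshold `p < alpha / n_edges`. Group sums are computed
#' with vectorized matrix operations; the statistic equals the classical
#' one-way ANOVA F.
#'
#' @param dataset A multisite `fc_dataset` (traveling rows are ignored).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `site_anova`: `F`, `p_value` (per edge),
#'   `significant` (Bonferroni mask), `significant_fraction`, `df`.
#' @export
site_effect_anova <- function(dataset, alpha = 0.05) {
  rows <- dataset$meta$dataset_kind == "multisite"
  Y <- dataset$values[rows, , drop = FALSE]
  site <- factor(dataset$meta$site_id[rows])
  counts <- table(site)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 sites with >= 2 subjects each", call. = FALSE)
  }
  n <- nrow(Y)
  k <- nlevels(site)
  G <- stats::model.matrix(~ site - 1)
  group_sums <- crossprod(G, Y)                      # k x E
  group_means <- group_sums / as.numeric(counts)
  grand_mean <- colMeans(Y)
  ssb <- colSums(as.numeric(counts) *
                   (group_means - rep(grand_mean, each = k))^2)
  sst <- colSums((Y - rep(grand_mean, each = n))^2)
  ssw <- sst - ssb
  df1 <- k - 1
  df2 <- n - k
  F_stat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  sig <- p < alpha / length(p)
  structure(list(F = F_stat, p_value = p, significant = sig,
                 significant_fraction = mean(sig), df = c(df1, df2)),
            class = "site_anova")
}
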