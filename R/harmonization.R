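# Four harmonizers for multisite connectivity:
#  - traveling-subject: subtracts the measurement bias m estimated by the
#    joint constrained-ridge decomposition (requires traveling data
#    covering every target site); sampling bias is left in the data.
#  - GLM: per-edge OLS with site indicators only; subtracts the full site
#    difference (measurement + sampling + any confounded disorder signal).
#  - adjusted GLM: per-edge OLS with site + diagnosis indicators
#    (HC baseline); subtracts the site term only.
#  - ComBat: parametric empirical-Bayes location-and-scale adjustment with
#    diagnosis covariates preserved.
# All models can be fitted on one dataset and applied to another.

new_harmonization_model <- function(method, site_terms, covariate_terms = NULL,
                                    scale_terms = NULL, intercept = NULL,
                                    extra = list()) {
  structure(c(list(method = method, site_terms = site_terms,
                   covariate_terms = covariate_terms,
                   scale_terms = scale_terms, intercept = intercept),
              extra),
            class = "harmonization_model")
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat(sprintf("<harmonization_model> method = %s; %d sites x %d edges\n",
              x$method, nrow(x$site_terms), ncol(x$site_terms)))
  invisible(x)
}

#' Traveling-subject harmonization model
#'
#' Fits the joint bias decomposition to the combined multisite +
#' traveling-subject dataset and keeps the estimated per-site measurement
#' bias; applying the model subtracts that bias, leaving sampling bias and
#' disorder factors untouched. Refuses to run when the traveling data do
#' not cover every multisite site (no extrapolation).
#'
#' @param dataset Combined multisite + traveling [fc_dataset()] (use
#'   [bind_datasets()]).
#' @param lambda Ridge weight for the decomposition.
#' @param decomposition Optional precomputed `bias_decomposition` for
#'   `dataset`.
#' @return A `harmonization_model` whose `site_terms` are the estimated
#'   measurement biases.
#' @export
fit_traveling_subject <- function(dataset, lambda = 1, decomposition = NULL) {
  meta <- dataset$meta
  multi_sites <- unique(meta$site_id[meta$dataset_kind == "multisite"])
  trav_sites <- unique(meta$site_id[meta$dataset_kind == "traveling"])
  uncovered <- setdiff(multi_sites, trav_sites)
  if (length(uncovered)) {
    stop("traveling data do not cover site(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  if (is.null(decomposition)) decomposition <- fit_all_edges(dataset, lambda)
  new_harmonization_model("traveling_subject", decomposition$measurement,
                          extra = list(lambda = decomposition$lambda))
}

# sum-to-zero site coding OLS; returns grand mean (const) and per-site
# offsets, optionally adjusting for diagnosis (HC baseline)
site_offset_fit <- function(dataset, adjust_diagnosis) {
  meta <- dataset$meta
  rows <- meta$dataset_kind == "multisite"
  Y <- dataset$values[rows, , drop = FALSE]
  site <- factor(meta$site_id[rows])
  counts <- table(site)
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    warning("dropping sites with no rows: ", paste(empty, collapse = ", "),
            call. = FALSE)
    site <- droplevels(site)
  }
  if (nlevels(site) < 2) stop("need at least 2 sites", call. = FALSE)
  n <- nrow(Y)
  S <- stats::model.matrix(~ site - 1)
  colnames(S) <- levels(site)
  if (adjust_diagnosis) {
    diag_f <- factor(meta$diagnosis[rows])
    diag_f <- stats::relevel(diag_f, ref = "HC")
    D <- if (nlevels(diag_f) > 1) {
      stats::model.matrix(~ diag_f)[, -1, drop = FALSE]
    } else {
      matrix(0, n, 0)
    }
    colnames(D) <- sub("^diag_f", "", colnames(D))
  } else {
    D <- matrix(0, n, 0)
  }
  # constrained OLS: site offsets sum to zero so const is the grand mean
  X <- cbind(const = 1, S, D)
  C <- matrix(0, 1, ncol(X))
  C[1, 1 + seq_len(ncol(S))] <- 1
  q <- nrow(C)
  H <- crossprod(X)
  K <- rbind(cbind(H, t(C)), cbind(C, matrix(0, q, q)))
  rhs <- rbind(crossprod(X, Y), matrix(0, q, ncol(Y)))
  sol <- tryCatch(solve(K, rhs), error = function(e) {
    warning("rank-deficient site/diagnosis design (perfect confounding); ",
            "using pseudo-inverse fit", call. = FALSE)
    MASS::ginv(K) %*% rhs
  })
  W <- sol[seq_len(ncol(X)), , drop = FALSE]
  rownames(W) <- colnames(X)
  list(intercept = W["const", ],
       site_terms = W[colnames(S), , drop = FALSE],
       covariate_terms = if (ncol(D)) W[colnames(D), , drop = FALSE] else NULL)
}

#' GLM harmonization model
#'
#' Per-edge ordinary least squares with site indicators only (sum-to-zero
#' site coding, so the intercept is the grand mean). Applying the model
#' subtracts the estimated site difference; after application, every
#' site's mean equals the grand mean at each edge. Because no biological
#' covariates are adjusted for, disorder signal confounded with site is
#' removed along with it.
#'
#' @param dataset A multisite `fc_dataset` (>= 2 sites).
#' @return A `harmonization_model`.
#' @export
fit_glm <- function(dataset) {
  fit <- site_offset_fit(dataset, adjust_diagnosis = FALSE)
  new_harmonization_model("glm", fit$site_terms, intercept = fit$intercept)
}

#' Adjusted GLM harmonization model
#'
#' Per-edge OLS with site indicators (sum-to-zero coding) plus diagnosis
#' indicators (HC baseline). Applying the model subtracts only the site
#' term, keeping the estimated disorder contrasts in the data.
#'
#' @param dataset A multisite `fc_dataset` with diagnosis labels.
#' @return A `harmonization_model` carrying the diagnosis coefficients in
#'   `covariate_terms`.
#' @export
fit_adjusted_glm <- function(dataset) {
  fit <- site_offset_fit(dataset, adjust_diagnosis = TRUE)
  new_harmonization_model("adjusted_glm", fit$site_terms,
                          covariate_terms = fit$covariate_terms,
                          intercept = fit$intercept)
}

combat_covariate_matrix <- function(diagnosis, levels) {
  D <- matrix(0, length(diagnosis), length(levels),
              dimnames = list(NULL, levels))
  hit <- diagnosis %in% levels
  D[cbind(which(hit), match(diagnosis[hit], levels))] <- 1
  D
}

#' ComBat harmonization model (parametric empirical Bayes)
#'
#' Location-and-scale batch adjustment: per edge, the data are standardized
#' using OLS estimates of the grand mean, diagnosis covariates and pooled
#' variance; per-site additive and multiplicative effects are estimated and
#' shrunk toward moment-matched priors (normal on the additive effect,
#' inverse-gamma on the multiplicative) by iterating the conditional
#' posterior means to convergence. Applying the model standardizes new
#' rows with the stored estimates, removes the shrunk site effects, and
#' restores the covariate scale, so site means and variances are aligned
#' while diagnosis trends are preserved.
#'
#' @param dataset A multisite `fc_dataset` (>= 2 sites, >= 2 rows per
#'   site).
#' @param tol Convergence tolerance of the EB iteration.
#' @param max_iter Maximum EB iterations.
#' @return A `harmonization_model` with additive `site_terms`, variance
#'   `scale_terms` (delta^2, strictly positive), diagnosis
#'   `covariate_terms`, `intercept`, and `pooled_sd`.
#' @export
fit_combat <- function(dataset, tol = 1e-4, max_iter = 100) {
  meta <- dataset$meta
  rows <- meta$dataset_kind == "multisite"
  Y <- dataset$values[rows, , drop = FALSE]
  site <- factor(meta$site_id[rows])
  counts <- table(site)
  if (nlevels(site) < 2) stop("need at least 2 sites", call. = FALSE)
  if (any(counts < 2)) {
    stop("every site needs >= 2 rows; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(Y)
  E <- ncol(Y)
  d_levels <- setdiff(sort(unique(meta$diagnosis[rows])), "HC")
  D <- combat_covariate_matrix(meta$diagnosis[rows], d_levels)
  B <- stats::model.matrix(~ site - 1)
  colnames(B) <- levels(site)
  X <- cbind(B, D)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, Y)),
                   error = function(e) MASS::ginv(crossprod(X)) %*%
                     crossprod(X, Y))
  gamma_hat <- beta[seq_len(ncol(B)), , drop = FALSE]       # site x E
  beta_cov <- if (length(d_levels)) {
    beta[ncol(B) + seq_along(d_levels), , drop = FALSE]
  } else {
    matrix(0, 0, E)
  }
  rownames(gamma_hat) <- colnames(B)
  # grand mean: sample-size weighted mean of site effects
  grand <- as.numeric(crossprod(as.numeric(counts) / n, gamma_hat))
  stand_mean <- rep(grand, each = n) +
    (if (length(d_levels)) D %*% beta_cov else 0)
  fitted <- X %*% beta
  var_pooled <- colMeans((Y - fitted)^2)
  if (any(var_pooled == 0)) {
    stop("zero pooled variance at some edges; cannot standardize",
         call. = FALSE)
  }
  Z <- (Y - stand_mean) / rep(sqrt(var_pooled), each = n)

  sites <- levels(site)
  gamma_star <- matrix(NA_real_, length(sites), E,
                       dimnames = list(sites, NULL))
  delta_star <- gamma_star
  for (s in sites) {
    zi <- Z[site == s, , drop = FALSE]
    ni <- nrow(zi)
    g_hat <- colMeans(zi)
    d_hat <- apply(zi, 2, stats::var)
    # moment-matched hyperpriors across edges
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m_d <- mean(d_hat)
    s2_d <- stats::var(d_hat)
    if (!is.finite(s2_d) || s2_d == 0 || !is.finite(t2) || t2 == 0) {
      # too few edges (or no spread) to moment-match the priors:
      # fall back to the unshrunk per-site estimates
      gamma_star[s, ] <- g_hat
      delta_star[s, ] <- pmax(d_hat, .Machine$double.eps)
      next
    }
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d
    g_old <- g_hat
    d_old <- d_hat
    change <- Inf
    it <- 0L
    while (change > tol) {
      it <- it + 1L
      if (it > max_iter) {
        stop(sprintf("ComBat EB iteration did not converge for site %s (change %g)",
                     s, change), call. = FALSE)
      }
      g_new <- (t2 * ni * g_hat + d_old * g_bar) / (t2 * ni + d_old)
      sum2 <- colSums((zi - rep(g_new, each = ni))^2)
      d_new <- (0.5 * sum2 + b_prior) / (ni / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new
      d_old <- d_new
    }
    gamma_star[s, ] <- g_old
    delta_star[s, ] <- d_old
  }
  new_harmonization_model(
    "combat",
    site_terms = gamma_star,
    covariate_terms = if (length(d_levels)) beta_cov else NULL,
    scale_terms = delta_star,
    intercept = grand,
    extra = list(pooled_sd = sqrt(var_pooled)))
}

#' Apply a fitted harmonization model to a dataset
#'
#' Row-wise, method-specific transform; metadata are unchanged. Additive
#' methods subtract their per-site term; ComBat standardizes with the
#' stored grand mean, covariates and pooled variance, removes the shrunk
#' additive site effect, divides by the site scale, and restores the
#' covariate-adjusted scale. Rows whose site is absent from the model are
#' an error by default; with `unknown_sites = "zero"` they are passed
#' through unadjusted (the all-zero indicator convention).
#'
#' @param dataset An `fc_dataset`.
#' @param model A `harmonization_model`.
#' @param unknown_sites `"error"` (default) or `"zero"`.
#' @return The harmonized `fc_dataset`.
#' @export
apply_harmonization <- function(dataset, model,
                                unknown_sites = c("error", "zero")) {
  unknown_sites <- match.arg(unknown_sites)
  stopifnot(inherits(model, "harmonization_model"))
  meta <- dataset$meta
  sites <- rownames(model$site_terms)
  known <- meta$site_id %in% sites
  if (!all(known)) {
    if (unknown_sites == "error") {
      stop("site(s) not in model: ",
           paste(unique(meta$site_id[!known]), collapse = ", "), call. = FALSE)
    }
  }
  Y <- dataset$values
  if (model$method == "combat") {
    n <- nrow(Y)
    E <- ncol(Y)
    d_levels <- rownames(model$covariate_terms)
    cov_part <- if (!is.null(model$covariate_terms)) {
      combat_covariate_matrix(meta$diagnosis, d_levels) %*%
        model$covariate_terms
    } else {
      matrix(0, n, E)
    }
    stand_mean <- rep(model$intercept, each = n) + cov_part
    Z <- (Y - stand_mean) / rep(model$pooled_sd, each = n)
    idx <- which(known)
    site_rows <- match(meta$site_id[idx], sites)
    Z[idx, ] <- (Z[idx, , drop = FALSE] -
                   model$site_terms[site_rows, , drop = FALSE]) /
      sqrt(model$scale_terms[site_rows, , drop = FALSE])
    Y <- Z * rep(model$pooled_sd, each = n) + stand_mean
  } else {
    idx <- which(known)
    site_rows <- match(meta$site_id[idx], sites)
    Y[idx, ] <- Y[idx, , drop = FALSE] -
      model$site_terms[site_rows, , drop = FALSE]
  }
  fc_dataset(Y, meta, dataset$edge_index)
}
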