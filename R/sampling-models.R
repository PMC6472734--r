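# Generative models for sampling-bias variance as a function of site
# sample size. With participants drawn from one common population the
# across-edge variance of a site's mean deviation is xi^2 / N_k; if each
# site samples its own subpopulation (site means beta_k ~ N(0, sigma^2))
# the variance is xi^2 / N_k + sigma^2. On the log10 scale:
#   single population:       y_k = -x_k + 2 log10(xi)
#   different subpopulation: y_k = log10(xi^2 10^-x_k + sigma^2)
# with x_k = log10(N_k), y_k = log10(v_k).

#' Construct site variance points
#'
#' @param site_id Character site labels.
#' @param n_subjects Per-site sample sizes (N_k >= 1).
#' @param variance Across-edge variance of the site's sampling-bias vector.
#' @return A data.frame of class `site_variance_points` with log-scale
#'   columns `x = log10(N_k)` and `y = log10(v_k)`.
#' @export
site_variance_points <- function(site_id, n_subjects, variance) {
  if (any(n_subjects < 1)) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(variance < 0)) stop("variance must be >= 0", call. = FALSE)
  structure(data.frame(site_id = as.character(site_id),
                       n_subjects = n_subjects, variance = variance,
                       x = log10(n_subjects), y = log10(variance),
                       stringsAsFactors = FALSE),
            class = c("site_variance_points", "data.frame"))
}

#' Site variance points from a fitted decomposition
#'
#' For each site carrying a sampling-bias vector of the requested class,
#' computes the variance of that vector across edges and pairs it with the
#' site's sample size from the dataset metadata.
#'
#' @param decomposition A `bias_decomposition`.
#' @param dataset The multisite `fc_dataset` the decomposition was fitted
#'   on (or the combined dataset).
#' @param class Diagnosis class: `"HC"`, `"MDD"`, or `"SCZ"`.
#' @return A `site_variance_points` data.frame.
#' @export
compute_site_variance_points <- function(decomposition, dataset,
                                         class = c("HC", "MDD", "SCZ")) {
  class <- match.arg(class)
  block <- decomposition[[paste0("sampling_", tolower(class))]]
  if (is.null(block)) {
    stop("sampling bias for class ", class, " is absent from the decomposition",
         call. = FALSE)
  }
  meta <- dataset$meta
  counts <- table(meta$site_id[meta$dataset_kind == "multisite" &
                                 meta$diagnosis == class])
  sites <- rownames(block)
  missing_sites <- setdiff(sites, names(counts))
  if (length(missing_sites)) {
    stop("no subjects of class ", class, " at sites: ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  }
  site_variance_points(sites, as.numeric(counts[sites]),
                       apply(block, 1, stats::var))
}

model_curve <- function(x, xi, sigma, model) {
  # both curves are log10 of the variance law v = xi^2 / N (+ sigma^2);
  # at sigma = 0 the subpopulation curve reduces to the single-population
  # line -x + 2 log10(xi)
  if (model == "single") -x + 2 * log10(xi)
  else log10(xi^2 * 10^-x + sigma^2)
}

#' Fit a sampling-bias population model
#'
#' Least squares on the log10-variance scale (the scale on which both model
#' curves are written), or optionally on the raw variance scale, using an
#' unconstrained quasi-Newton search over log-parameters to keep xi and
#' sigma positive. Residuals `phi_k = v_k - v_hat_k` are returned on the
#' raw variance scale, as used by the information criteria.
#'
#' @param points A `site_variance_points` data.frame.
#' @param model `"single"` (parameter xi; q = 1) or `"different"`
#'   (parameters xi, sigma; q = 2).
#' @param loss_scale `"log"` (default) or `"variance"`.
#' @return Object of class `population_fit`: `model`, `xi`, `sigma`,
#'   `q`, `residuals` (raw scale), `fitted_variance`, `aicc`, `bic`,
#'   `points`.
#' @export
fit_population_model <- function(points, model = c("single", "different"),
                                 loss_scale = c("log", "variance")) {
  model <- match.arg(model)
  loss_scale <- match.arg(loss_scale)
  q <- if (model == "single") 1L else 2L
  if (nrow(points) < q + 1) {
    stop("need at least q + 1 = ", q + 1, " sites", call. = FALSE)
  }
  x <- points$x
  y <- points$y
  v <- points$variance
  objective <- function(par) {
    xi <- exp(par[1])
    sigma <- if (model == "different") exp(par[2]) else 0
    if (loss_scale == "log") {
      sum((y - model_curve(x, xi, sigma, model))^2)
    } else {
      sum((v - 10^model_curve(x, xi, sigma, model))^2)
    }
  }
  # closed-form start for the single model; the different model's surface
  # has a flat large-sigma basin, so it is fitted from several sigma
  # starts and the best optimum is kept
  xi0 <- 10^(mean(y + x) / 2)
  starts <- if (model == "single") {
    list(log(xi0))
  } else {
    sigma_asym <- sqrt(10^max(y))  # flat asymptote level at large N
    lapply(c(1e-3 * xi0, 1e-1 * xi0, xi0, sigma_asym),
           function(s0) c(log(xi0), log(s0)))
  }
  opts <- lapply(starts, function(st) {
    tryCatch(stats::optim(st, objective, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             error = function(e) NULL)
  })
  opts <- Filter(function(o) !is.null(o) && o$convergence == 0, opts)
  if (!length(opts)) {
    stop("population-model fit did not converge from any start", call. = FALSE)
  }
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  xi <- exp(opt$par[1])
  sigma <- if (model == "different") exp(opt$par[2]) else 0
  fitted_v <- 10^model_curve(x, xi, sigma, model)
  phi <- v - fitted_v
  ic <- information_criteria(phi, q)
  structure(list(model = model, xi = xi, sigma = sigma, q = q,
                 residuals = phi, fitted_variance = fitted_v,
                 aicc = ic[["aicc"]], bic = ic[["bic"]],
                 loss_scale = loss_scale, points = points),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> %s model: xi = %.4g, sigma = %.4g, AICc = %.2f, BIC = %.2f\n",
              x$model, x$xi, x$sigma, x$aicc, x$bic))
  invisible(x)
}

#' Small-sample information criteria for a population-model fit
#'
#' Under a Gaussian error assumption on the raw-scale residuals `phi_k`,
#' `AICc = sum(ln phi_k^2) + 2q + 2q(q+1)/(K - q - 1)` and
#' `BIC = sum(ln phi_k^2) + q ln(K)` with K sites. A zero residual makes a
#' criterion `-Inf`, flagged as a degenerate perfect fit.
#'
#' @param fit A `population_fit`, or a numeric vector of raw-scale
#'   residuals (then `q` must be given).
#' @param q Parameter count (1 or 2) when `fit` is a residual vector.
#' @return Named numeric vector `c(aicc, bic)`.
#' @export
information_criteria <- function(fit, q = NULL) {
  if (inherits(fit, "population_fit")) {
    phi <- fit$residuals
    q <- fit$q
  } else {
    phi <- fit
    if (is.null(q)) stop("q required for a residual vector", call. = FALSE)
  }
  K <- length(phi)
  if (K - q - 1 <= 0) stop("AICc undefined: K <= q + 1", call. = FALSE)
  if (any(phi == 0)) {
    warning("zero residual: criteria are -Inf (degenerate perfect fit)",
            call. = FALSE)
  }
  s <- sum(log(phi^2))
  c(aicc = s + 2 * q + 2 * q * (q + 1) / (K - q - 1),
    bic = s + q * log(K))
}

#' Leave-one-site-out prediction of sampling-bias variance
#'
#' For each site, fits the model on the remaining sites and predicts the
#' held-out site's variance from its sample size; reports absolute errors.
#' When both models are requested, the two error vectors are compared with
#' a one-tailed paired Wilcoxon signed-rank test of the hypothesis that the
#' different-subpopulation model has smaller absolute error.
#'
#' @param points A `site_variance_points` data.frame (>= 3 sites).
#' @param models Character vector of models to evaluate.
#' @param loss_scale Passed to [fit_population_model()].
#' @return List of class `loso_cv`: `errors` (site x model matrix of
#'   absolute errors), `predicted` (site x model), and `wilcoxon`
#'   (htest or NULL).
#' @export
loso_cv_predict <- function(points, models = c("single", "different"),
                            loss_scale = "log") {
  if (nrow(points) < 3) stop("need at least 3 sites", call. = FALSE)
  K <- nrow(points)
  pred <- matrix(NA_real_, K, length(models),
                 dimnames = list(points$site_id, models))
  for (m in models) {
    for (k in seq_len(K)) {
      fit <- tryCatch(
        fit_population_model(points[-k, , drop = FALSE], model = m,
                             loss_scale = loss_scale),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("fold %d (%s model) failed; excluded", k, m),
                call. = FALSE)
        next
      }
      pred[k, m] <- 10^model_curve(points$x[k], fit$xi, fit$sigma, m)
    }
  }
  errors <- abs(pred - points$variance)
  wt <- NULL
  if (all(c("single", "different") %in% models)) {
    ok <- stats::complete.cases(errors[, c("single", "different")])
    wt <- stats::wilcox.test(errors[ok, "different"], errors[ok, "single"],
                             paired = TRUE, alternative = "less",
                             exact = FALSE)
  }
  structure(list(errors = errors, predicted = pred, wilcoxon = wt),
            class = "loso_cv")
}
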