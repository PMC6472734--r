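# Twofold cross-validation of harmonization performance: fit the
# harmonizer on one half (the estimating dataset; the traveling-subject
# method additionally uses one half of the traveling sessions), apply it
# to the other half (the testing dataset), refit the full bias
# decomposition on the testing dataset, and summarize the residual
# measurement bias and the signal-to-noise ratios. Repeated with the
# halves exchanged.

#' Site-stratified twofold split
#'
#' Multisite rows are split ~50/50 within every site (an odd row count
#' rounds the extra row to fold 1; a single-row site goes to fold 1 with a
#' warning). Traveling rows are split within every site x participant
#' cell, so both halves preserve the site and subject proportions; cells
#' with a single session are assigned whole to fold 1 with a warning.
#'
#' @param dataset Multisite `fc_dataset`.
#' @param traveling Traveling `fc_dataset`.
#' @param seed Integer seed governing both splits.
#' @return List of class `cv_split` with logical vectors
#'   `multisite_fold1`, `traveling_fold1`, and `seed`.
#' @export
make_split <- function(dataset, traveling, seed = 1) {
  set.seed(seed)
  split_within <- function(groups, what) {
    fold1 <- logical(length(groups))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) == 1) {
        warning(sprintf("%s group '%s' has a single row; assigned to fold 1",
                        what, g), call. = FALSE)
        fold1[idx] <- TRUE
        next
      }
      take <- ceiling(length(idx) / 2)
      fold1[sample(idx, take)] <- TRUE
    }
    fold1
  }
  ms_fold1 <- split_within(dataset$meta$site_id, "site")
  tr_fold1 <- split_within(paste(traveling$meta$site_id,
                                 traveling$meta$participant_id, sep = "|"),
                           "site x participant")
  structure(list(multisite_fold1 = ms_fold1, traveling_fold1 = tr_fold1,
                 seed = seed),
            class = "cv_split")
}

# mean across sites of the per-site magnitude SD of a factor block
mean_level_sd <- function(block) {
  if (is.null(block)) return(NA_real_)
  mean(sqrt(rowMeans((block - rowMeans(block))^2)))
}

# summarize a testing-set decomposition into the evaluation statistics
evaluation_stats <- function(decomposition) {
  sd_m <- mean_level_sd(decomposition$measurement)
  sd_p <- mean_level_sd(decomposition$participant)
  sd_d <- if (is.null(decomposition$disorder)) NA_real_ else {
    mean(sqrt(rowMeans(decomposition$disorder^2)))
  }
  c(measurement_sd = sd_m,
    ratio_participant = sd_m / sd_p,
    ratio_disorder = sd_m / sd_d)
}

#' Twofold cross-validation of harmonization methods
#'
#' For each fold direction: the traveling-subject model is fitted on the
#' estimating dataset (multisite fold + its traveling half); GLM, adjusted
#' GLM, and ComBat are fitted on the multisite fold only. Each fitted
#' model is applied to the testing dataset (the other multisite fold
#' concatenated with the other traveling half; rows at traveling-only
#' sites a model does not know are passed through unadjusted). The full
#' bias decomposition is then refitted on the testing dataset and the mean
#' per-site SD of the measurement bias plus the two signal-to-noise ratios
#' (measurement / participant and measurement / disorder SD) are recorded.
#' `"raw"` evaluates the unharmonized testing dataset.
#'
#' @param dataset Multisite `fc_dataset`.
#' @param traveling Traveling `fc_dataset`.
#' @param methods Subset of `c("raw", "traveling", "glm", "adjusted_glm",
#'   "combat")`.
#' @param lambda Ridge weight used in every bias-decomposition fit.
#' @param seed Split seed.
#' @param split Optional precomputed `cv_split`.
#' @return Object of class `evaluation_report`: `stats` data.frame with
#'   one row per (method, fold) -- columns `method`, `fold`,
#'   `measurement_sd`, `ratio_participant`, `ratio_disorder`, `failed` --
#'   and the `split`.
#' @export
run_cv_evaluation <- function(dataset, traveling,
                              methods = c("raw", "traveling", "glm",
                                          "adjusted_glm", "combat"),
                              lambda = 1, seed = 1, split = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(split)) split <- make_split(dataset, traveling, seed)
  out <- list()
  for (fold in 1:2) {
    est_ms <- subset_rows(dataset, split$multisite_fold1 == (fold == 1))
    tst_ms <- subset_rows(dataset, split$multisite_fold1 != (fold == 1))
    est_tr <- subset_rows(traveling, split$traveling_fold1 == (fold == 1))
    tst_tr <- subset_rows(traveling, split$traveling_fold1 != (fold == 1))
    testing <- bind_datasets(tst_ms, tst_tr)
    for (method in methods) {
      row <- tryCatch({
        harmonized <- switch(
          method,
          raw = testing,
          traveling = {
            model <- fit_traveling_subject(bind_datasets(est_ms, est_tr),
                                           lambda = lambda)
            apply_harmonization(testing, model)
          },
          glm = apply_harmonization(testing, fit_glm(est_ms),
                                    unknown_sites = "zero"),
          adjusted_glm = apply_harmonization(testing, fit_adjusted_glm(est_ms),
                                             unknown_sites = "zero"),
          combat = apply_harmonization(testing, fit_combat(est_ms),
                                       unknown_sites = "zero"))
        dec <- fit_all_edges(harmonized, lambda)
        c(evaluation_stats(dec), failed = 0)
      }, error = function(e) {
        warning(sprintf("method %s failed in fold %d: %s",
                        method, fold, conditionMessage(e)), call. = FALSE)
        c(measurement_sd = NA_real_, ratio_participant = NA_real_,
          ratio_disorder = NA_real_, failed = 1)
      })
      out[[length(out) + 1L]] <- data.frame(
        method = method, fold = fold, t(row), stringsAsFactors = FALSE)
    }
  }
  structure(list(stats = do.call(rbind, out), split = split,
                 lambda = lambda),
            class = "evaluation_report")
}

#' Percent bias reduction and signal-to-noise improvement versus raw
#'
#' Reduction is `100 (SD_raw - SD_method) / SD_raw` per fold, averaged
#' over folds; the signal-to-noise improvements are computed analogously
#' on the measurement/participant and measurement/disorder SD ratios (a
#' smaller ratio is better, so a positive value is an improvement).
#'
#' @param report An `evaluation_report` containing the `"raw"` method.
#' @return Data.frame with one row per non-raw method: `method`,
#'   `bias_reduction_pct`, `snr_participant_improvement_pct`,
#'   `snr_disorder_improvement_pct`.
#' @export
reduction_and_snr <- function(report) {
  stats <- report$stats
  if (!"raw" %in% stats$method) stop("'raw' method missing", call. = FALSE)
  raw <- stats[stats$method == "raw", ]
  if (any(raw$measurement_sd == 0, na.rm = TRUE)) {
    stop("raw measurement-bias SD is zero; percentages undefined",
         call. = FALSE)
  }
  pct <- function(method_rows, col) {
    per_fold <- vapply(method_rows$fold, function(f) {
      base <- raw[[col]][raw$fold == f]
      100 * (base - method_rows[[col]][method_rows$fold == f]) / base
    }, numeric(1))
    mean(per_fold)
  }
  methods <- setdiff(unique(stats$method), "raw")
  do.call(rbind, lapply(methods, function(m) {
    rows <- stats[stats$method == m, ]
    data.frame(method = m,
               bias_reduction_pct = pct(rows, "measurement_sd"),
               snr_participant_improvement_pct = pct(rows, "ratio_participant"),
               snr_disorder_improvement_pct = pct(rows, "ratio_disorder"),
               stringsAsFactors = FALSE)
  }))
}
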