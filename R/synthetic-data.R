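# Synthetic multisite + traveling-subject connectivity data with known
# ground truth, following the generative structure of the decomposition
# model: each edge is independent Gaussian around the sum of its factor
# terms. Defaults reproduce the study design scale: a unified-protocol
# multisite sample (HC at six sites, MDD at three, SCZ at three, ASD at
# one) and a 12-site x 9-participant traveling-subject sample with the
# 411-session schedule.

#' Default traveling-subject session schedule
#'
#' Nine participants scanned at 12 sites: three sessions at nine sites, two
#' sessions at two sites, and five cycles of three sessions at one site --
#' with one participant one cycle short there -- totalling 411 sessions.
#'
#' @return A data.frame of class `traveling_schedule` with columns
#'   `participant_id`, `site_id`, `n_sessions`.
#' @examples
#' sum(default_traveling_schedule()$n_sessions)  # 411
#' @export
default_traveling_schedule <- function() {
  participants <- sprintf("TS%02d", 1:9)
  cycle_site <- "ST01"
  two_session_sites <- c("ST02", "ST03")
  three_session_sites <- sprintf("ST%02d", 4:12)
  rows <- do.call(rbind, lapply(seq_along(participants), function(k) {
    rbind(
      data.frame(participant_id = participants[k], site_id = cycle_site,
                 n_sessions = if (k == length(participants)) 4L * 3L else 5L * 3L),
      data.frame(participant_id = participants[k], site_id = two_session_sites,
                 n_sessions = 2L),
      data.frame(participant_id = participants[k],
                 site_id = three_session_sites, n_sessions = 3L)
    )
  }))
  structure(rows, class = c("traveling_schedule", "data.frame"))
}

#' Default multisite design emulating the unified-protocol study table
#'
#' Per-site participant counts by diagnosis class for the six
#' unified-protocol sites: HC at all six, MDD at three, SCZ at three, ASD
#' at a single site (whose sampling bias is therefore confounded with the
#' ASD disorder factor).
#'
#' @return A data.frame with columns `site_id`, `diagnosis`, `n`.
#' @export
default_multisite_design <- function() {
  rbind(
    data.frame(site_id = c("ST04", "ST05", "ST06", "ST07", "ST08", "ST09"),
               diagnosis = "HC", n = c(31L, 77L, 10L, 35L, 40L, 142L)),
    data.frame(site_id = c("ST06", "ST07", "ST09"),
               diagnosis = "MDD", n = c(38L, 9L, 34L)),
    data.frame(site_id = c("ST07", "ST08", "ST09"),
               diagnosis = "SCZ", n = c(22L, 12L, 14L)),
    data.frame(site_id = "ST08", diagnosis = "ASD", n = 49L)
  )
}

#' Scale-setting defaults for the synthetic generator
#'
#' Standard deviations (Fisher-z units) placing simulations in the regime
#' of the study: participant factor 0.0662, measurement bias 0.0411,
#' disorder factors 0.0328 (MDD), 0.0377 (SCZ), 0.0297 (ASD). Sampling
#' bias arises from the different-subpopulation model with within-population
#' SD `xi` (shared with the participant factor) and between-subpopulation SD
#' `sigma = 0.02`, so realized per-site sampling-bias SDs
#' `sqrt(xi^2 / N_k + sigma^2)` span roughly 0.021-0.029 over the default
#' site sizes. Scan-to-scan noise SD 0.03.
#'
#' @return Named list of generator parameters.
#' @export
reference_scale_params <- function() {
  list(sd_m = 0.0411, sd_p = 0.0662,
       sd_d = c(MDD = 0.0328, SCZ = 0.0377, ASD = 0.0297),
       xi = 0.0662, sigma = 0.02, noise_sd = 0.03, const_sd = 0.25)
}

# center a (levels x edges) matrix so each edge sums to zero over levels
center_block <- function(m) {
  if (is.null(m) || nrow(m) < 2) return(m)
  sweep(m, 2, colMeans(m), "-")
}

#' Draw the generating ground truth for a synthetic study
#'
#' @param traveling_sites All traveling-subject site ids (superset of the
#'   multisite sites).
#' @param multisite_design Data.frame like [default_multisite_design()].
#' @param participants Traveling participant ids.
#' @param n_edges Number of connectivity edges.
#' @param params Generator parameters ([reference_scale_params()] defaults).
#' @param model Sampling-bias population model: `"different"` draws site
#'   subpopulation means `beta_k ~ N(0, sigma^2)`; `"single"` sets them to 0.
#' @param seed Integer seed.
#' @return Object of class `ground_truth` holding per-edge factor vectors
#'   (measurement bias per site, subpopulation means per site x class,
#'   disorder factors, participant factors), the intercept, noise SD and
#'   population parameters. Bias blocks are re-centered to sum to zero
#'   across sites, matching the estimator's constraints.
#' @export
generate_ground_truth <- function(traveling_sites = sprintf("ST%02d", 1:12),
                                  multisite_design = default_multisite_design(),
                                  participants = sprintf("TS%02d", 1:9),
                                  n_edges = 1000,
                                  params = reference_scale_params(),
                                  model = c("different", "single"),
                                  seed = 1) {
  model <- match.arg(model)
  stopifnot(all(multisite_design$site_id %in% traveling_sites))
  set.seed(seed)
  draw <- function(levels, sd) {
    matrix(stats::rnorm(length(levels) * n_edges, 0, sd),
           length(levels), n_edges, dimnames = list(levels, NULL))
  }
  # centering across K levels deflates each level's SD by sqrt(1 - 1/K);
  # pre-inflate so the realized per-level SDs match the requested scale
  draw_centered <- function(levels, sd) {
    K <- length(levels)
    center_block(draw(levels, sd / sqrt(1 - 1 / K)))
  }
  measurement <- draw_centered(traveling_sites, params$sd_m)
  participant <- draw_centered(participants, params$sd_p)
  d_levels <- intersect(names(params$sd_d), unique(multisite_design$diagnosis))
  disorder <- do.call(rbind, lapply(d_levels, function(l) {
    draw(l, params$sd_d[[l]])
  }))
  # subpopulation means per class x site (different-subpopulation model)
  beta <- list()
  for (cl in unique(multisite_design$diagnosis)) {
    sites_cl <- multisite_design$site_id[multisite_design$diagnosis == cl]
    beta[[cl]] <- if (model == "different") {
      draw(sites_cl, params$sigma)
    } else {
      matrix(0, length(sites_cl), n_edges, dimnames = list(sites_cl, NULL))
    }
  }
  structure(list(
    measurement = measurement,
    participant = participant,
    disorder = disorder,
    beta = beta,
    intercept = stats::rnorm(n_edges, 0, params$const_sd),
    params = params,
    model = model,
    multisite_design = multisite_design,
    traveling_sites = traveling_sites,
    participants = participants,
    n_edges = n_edges,
    seed = seed
  ), class = "ground_truth")
}

#' Generate a synthetic multisite dataset
#'
#' Each participant's edge vector is the intercept plus the site's
#' measurement bias, the participant's individual deviation drawn
#' `N(beta_(class,site), xi^2)` (whose site mean is the realized sampling
#' bias), the disorder factor for non-HC rows, and Gaussian scan noise.
#' The realized per-site sampling biases (site means of the individual
#' deviations, centered across sites per class) are recorded in the
#' returned ground truth as `sampling_hc`, `sampling_mdd`, `sampling_scz`
#' so estimator recovery can be checked against what the estimator
#' actually targets.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param seed Integer seed.
#' @return List with `dataset` (an `fc_dataset`) and `truth` (the input
#'   with realized sampling-bias blocks added).
#' @export
generate_multisite <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  design <- truth$multisite_design
  if (sum(design$n) == 0) stop("all class counts are zero", call. = FALSE)
  n_edges <- truth$n_edges
  params <- truth$params
  rows <- list()
  meta <- list()
  deviations <- list()  # per class: list of site -> n x E deviation draws
  counter <- 0L
  for (r in seq_len(nrow(design))) {
    site <- design$site_id[r]
    cl <- design$diagnosis[r]
    n <- design$n[r]
    if (n == 0) next
    dev <- matrix(stats::rnorm(n * n_edges, 0, params$xi), n, n_edges)
    dev <- sweep(dev, 2, truth$beta[[cl]][site, ], "+")
    deviations[[cl]][[site]] <- dev
    base <- truth$intercept + truth$measurement[site, ]
    if (cl %in% rownames(truth$disorder)) base <- base + truth$disorder[cl, ]
    vals <- sweep(dev, 2, base, "+") +
      matrix(stats::rnorm(n * n_edges, 0, params$noise_sd), n, n_edges)
    ids <- sprintf("MS%05d", counter + seq_len(n))
    counter <- counter + n
    rows[[length(rows) + 1L]] <- vals
    meta[[length(meta) + 1L]] <- data.frame(
      row_id = ids, participant_id = ids, site_id = site, diagnosis = cl,
      dataset_kind = "multisite", session_id = "1",
      stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  # realized sampling bias: per-class site means of individual deviations,
  # centered across sites (the estimator's convention)
  for (cl in c("HC", "MDD", "SCZ")) {
    if (is.null(deviations[[cl]]) || length(deviations[[cl]]) < 2) next
    site_means <- do.call(rbind, lapply(deviations[[cl]], colMeans))
    rownames(site_means) <- names(deviations[[cl]])
    truth[[paste0("sampling_", tolower(cl))]] <- center_block(site_means)
  }
  n_nodes <- nodes_for_edges(n_edges)
  edge_index <- truncated_edge_index(n_nodes, n_edges)
  list(dataset = fc_dataset(values, meta, edge_index), truth = truth)
}

#' Generate a synthetic traveling-subject dataset
#'
#' Each session row is the intercept plus the site's measurement bias, the
#' participant factor, and scan noise.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param schedule A [default_traveling_schedule()]-style data.frame.
#' @param seed Integer seed.
#' @return An `fc_dataset` of traveling sessions.
#' @export
generate_traveling <- function(truth, schedule = default_traveling_schedule(),
                               seed = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(schedule) == 0) stop("schedule is empty", call. = FALSE)
  missing_p <- setdiff(unique(schedule$participant_id), truth$participants)
  if (length(missing_p)) {
    stop("participants absent from ground truth: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  n_edges <- truth$n_edges
  total <- sum(schedule$n_sessions)
  values <- matrix(0, total, n_edges)
  meta <- data.frame(row_id = character(total), participant_id = character(total),
                     site_id = character(total), diagnosis = "HC",
                     dataset_kind = "traveling", session_id = character(total),
                     stringsAsFactors = FALSE)
  at <- 0L
  for (r in seq_len(nrow(schedule))) {
    ns <- schedule$n_sessions[r]
    if (ns == 0) next
    site <- schedule$site_id[r]
    pid <- schedule$participant_id[r]
    base <- truth$intercept + truth$measurement[site, ] +
      truth$participant[pid, ]
    vals <- sweep(matrix(stats::rnorm(ns * n_edges, 0, truth$params$noise_sd),
                         ns, n_edges), 2, base, "+")
    idx <- at + seq_len(ns)
    values[idx, ] <- vals
    meta$row_id[idx] <- sprintf("TR_%s_%s_s%02d", pid, site, seq_len(ns))
    meta$participant_id[idx] <- pid
    meta$site_id[idx] <- site
    meta$session_id[idx] <- as.character(seq_len(ns))
    at <- at + ns
  }
  n_nodes <- nodes_for_edges(n_edges)
  fc_dataset(values, meta, truncated_edge_index(n_nodes, n_edges))
}

#' Generate a paired multisite + traveling study with ground truth
#'
#' Convenience wrapper drawing one ground truth and both datasets from a
#' single seed.
#'
#' @inheritParams generate_ground_truth
#' @param schedule Traveling session schedule.
#' @return List with `multisite`, `traveling` (both `fc_dataset`) and
#'   `truth`.
#' @export
generate_study <- function(n_edges = 1000, params = reference_scale_params(),
                           model = "different",
                           multisite_design = default_multisite_design(),
                           schedule = default_traveling_schedule(),
                           seed = 1) {
  truth <- generate_ground_truth(
    traveling_sites = sort(unique(c(schedule$site_id,
                                    multisite_design$site_id))),
    multisite_design = multisite_design,
    participants = sort(unique(schedule$participant_id)),
    n_edges = n_edges, params = params, model = model, seed = seed)
  ms <- generate_multisite(truth, seed = seed + 1000L)
  tr <- generate_traveling(ms$truth, schedule, seed = seed + 2000L)
  list(multisite = ms$dataset, traveling = tr, truth = ms$truth)
}

#' Simulate per-site sampling-bias variance points
#'
#' Draws `n_subjects[k]` subject vectors per site under the chosen
#' population model (`c_jk ~ N(beta_k, xi^2 I)` with `beta_k ~ N(0,
#' sigma^2 I)` for the different-subpopulation model, `beta_k = 0` for the
#' single-population model), averages them per site and returns the
#' across-edge variance of each site mean, the quantity whose expectation
#' is `xi^2 / N_k + sigma^2`.
#'
#' @param xi Within-population SD (>= 0).
#' @param sigma Between-subpopulation SD (>= 0; ignored for
#'   `model = "single"`).
#' @param n_subjects Named or unnamed vector of per-site sample sizes.
#' @param n_edges Number of edges.
#' @param model `"different"` or `"single"`.
#' @param seed Integer seed.
#' @return A data.frame of class `site_variance_points` with columns
#'   `site_id`, `n_subjects`, `variance`, `x` (log10 N), `y` (log10 v).
#' @export
generate_population_points <- function(xi, sigma, n_subjects, n_edges = 2000,
                                       model = c("different", "single"),
                                       seed = 1) {
  model <- match.arg(model)
  if (xi < 0 || sigma < 0) stop("xi and sigma must be >= 0", call. = FALSE)
  if (any(n_subjects <= 0)) stop("site sizes must be positive", call. = FALSE)
  set.seed(seed)
  sites <- names(n_subjects)
  if (is.null(sites)) sites <- sprintf("ST%02d", seq_along(n_subjects))
  v <- vapply(seq_along(n_subjects), function(k) {
    beta <- if (model == "different") stats::rnorm(n_edges, 0, sigma) else 0
    subj <- matrix(stats::rnorm(n_subjects[k] * n_edges, 0, xi),
                   n_subjects[k], n_edges)
    site_mean <- colMeans(subj) + beta
    stats::var(site_mean)
  }, numeric(1))
  site_variance_points(sites, as.numeric(n_subjects), v)
}

#' Generate ROI time series with target correlations and spiky motion
#'
#' Gaussian latent-factor generator: the population correlation matrix of
#' the returned series matches `target` (which must be positive
#' semi-definite); motion parameters are small Gaussian wiggles with
#' occasional large spikes to exercise scrubbing.
#'
#' @param target K x K target correlation matrix (unit diagonal).
#' @param n_volumes Number of volumes T (>= 50).
#' @param tr_seconds Repetition time.
#' @param spike_rate Fraction of volumes receiving a motion spike.
#' @param seed Integer seed.
#' @return List with `series` (T x K), `motion` (T x 6), `tr_seconds`.
#' @export
generate_roi_timeseries <- function(target, n_volumes = 240, tr_seconds = 2.5,
                                    spike_rate = 0.05, seed = 1) {
  if (n_volumes < 50) stop("need at least 50 volumes", call. = FALSE)
  target <- as.matrix(target)
  ev <- eigen(target, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("target correlation matrix is not positive semi-definite; ",
         "project to the nearest PSD matrix first", call. = FALSE)
  }
  set.seed(seed)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(target))
  series <- matrix(stats::rnorm(n_volumes * nrow(target)), n_volumes) %*% t(L)
  motion <- matrix(stats::rnorm(n_volumes * 6, 0, 0.02), n_volumes, 6)
  motion[, 4:6] <- motion[, 4:6] / 50
  spikes <- which(stats::runif(n_volumes) < spike_rate)
  motion[spikes, 1] <- motion[spikes, 1] + 1.0
  motion <- apply(motion, 2, cumsum)  # random-walk head position
  list(series = series, motion = motion, tr_seconds = tr_seconds)
}

# smallest node count whose full lower triangle holds >= n_edges edges
nodes_for_edges <- function(n_edges) {
  k <- ceiling((1 + sqrt(1 + 8 * n_edges)) / 2)
  as.integer(k)
}

# edge index truncated to the first n_edges pairs (keeps synthetic data
# compact for arbitrary edge counts)
truncated_edge_index <- function(n_nodes, n_edges) {
  idx <- build_edge_index(n_nodes)
  if (n_edges > idx$n_edges) stop("n_edges exceeds full lower triangle",
                                  call. = FALSE)
  idx$i <- idx$i[seq_len(n_edges)]
  idx$j <- idx$j[seq_len(n_edges)]
  idx$labels <- idx$labels[seq_len(n_edges)]
  idx$n_edges <- as.integer(n_edges)
  idx
}
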