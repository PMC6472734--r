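# PCA projection of connectivity datasets for visualizing site and
# disorder structure before and after harmonization.

#' PCA projection with site/diagnosis group means
#'
#' Centered (unscaled) principal component analysis of the row-by-edge
#' matrix; all edges share Fisher-z units, so no per-edge scaling is
#' applied. Scores are returned for every row together with the averages
#' across HCs within each site and across rows within each non-HC
#' diagnosis. Each component's sign is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param dataset An `fc_dataset`.
#' @param n_components Number of components to keep (default 2).
#' @return Object of class `pca_projection`: `loadings` (edges x
#'   components), `scores` (rows x components), `explained` (variance
#'   fractions for the kept components), `explained_all` (all components),
#'   `site_hc_means`, `diagnosis_means`, `center`.
#' @export
project_pca <- function(dataset, n_components = 2) {
  Y <- dataset$values
  if (nrow(Y) <= n_components) {
    stop("need more rows than components", call. = FALSE)
  }
  if (all(apply(Y, 2, stats::sd) == 0)) {
    stop("constant dataset: principal components are degenerate", call. = FALSE)
  }
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  explained_all <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # reproducible sign convention
  for (c_ in seq_len(k)) {
    top <- which.max(abs(load[, c_]))
    if (load[top, c_] < 0) {
      load[, c_] <- -load[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  meta <- dataset$meta
  hc <- meta$diagnosis == "HC"
  site_means <- do.call(rbind, lapply(sort(unique(meta$site_id[hc])),
    function(s) colMeans(scores[hc & meta$site_id == s, , drop = FALSE])))
  rownames(site_means) <- sort(unique(meta$site_id[hc]))
  d_levels <- sort(setdiff(unique(meta$diagnosis), "HC"))
  diag_means <- if (length(d_levels)) {
    out <- do.call(rbind, lapply(d_levels, function(d)
      colMeans(scores[meta$diagnosis == d, , drop = FALSE])))
    rownames(out) <- d_levels
    out
  } else {
    NULL
  }
  structure(list(loadings = load, scores = scores,
                 explained = explained_all[seq_len(k)],
                 explained_all = explained_all,
                 site_hc_means = site_means, diagnosis_means = diag_means,
                 center = pc$center),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> %d components; explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}
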