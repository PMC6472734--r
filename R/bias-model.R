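# Joint decomposition of site differences into measurement bias, sampling
# bias, disorder factors and participant factors.
#
# Per edge, connectivity is modeled as
#   y = x_m' m + x_shc' s_hc + x_smdd' s_mdd + x_sscz' s_scz
#       + x_d' d + x_p' p + const + e,      e ~ N(0, gamma^-1)
# with 1-of-K indicators (all-zero when a row does not belong to a class)
# and hard sum-to-zero constraints over sites for m and each sampling-bias
# class, over participants for p, and d(HC) = 0 via HC-baseline coding.
# Multisite rows carry m, s and d; traveling rows carry m and p. Because m
# and s are collinear within the multisite rows alone, the design is
# rank-deficient and the fit uses L2 regularization (ridge weight lambda).

#' Assemble the joint design matrix and constraint set
#'
#' Builds indicator blocks sized by the observed levels: measurement bias
#' over all sites, sampling bias per diagnosis class over the sites where
#' that class is observed in the multisite data (a class seen at fewer than
#' two sites gets no sampling block and is absorbed by its disorder factor,
#' as for ASD), disorder factors for every non-HC diagnosis observed, and
#' participant factors for the traveling participants. The final column is
#' the intercept.
#'
#' @param dataset An [fc_dataset()] mixing multisite and traveling rows.
#' @return A list of class `bias_design`: `X` (n x p design), `C`
#'   (constraint matrix, rows summing each constrained block to zero),
#'   `blocks` (named list of column indices), `levels` (named list of level
#'   labels), `penalty` (diagonal of the ridge penalty; 0 for the
#'   intercept).
#' @export
assemble_design <- function(dataset) {
  stopifnot(inherits(dataset, "fc_dataset"))
  meta <- dataset$meta
  multi <- meta$dataset_kind == "multisite"
  trav <- meta$dataset_kind == "traveling"

  all_sites <- sort(unique(meta$site_id))
  sampling_classes <- c("HC", "MDD", "SCZ")
  s_levels <- list()
  for (cl in sampling_classes) {
    sites_cl <- sort(unique(meta$site_id[multi & meta$diagnosis == cl]))
    if (length(sites_cl) >= 2) {
      s_levels[[cl]] <- sites_cl
    } else if (length(sites_cl) == 1) {
      warning(sprintf(
        "diagnosis %s observed at a single site (%s); no sampling-bias block",
        cl, sites_cl), call. = FALSE)
    }
  }
  d_levels <- sort(setdiff(unique(meta$diagnosis[multi]), "HC"))
  p_levels <- sort(unique(meta$participant_id[trav]))

  blocks <- list()
  levels <- list(m = all_sites)
  col_names <- paste0("m:", all_sites)
  blocks$m <- seq_along(all_sites)
  for (cl in names(s_levels)) {
    nm <- paste0("s_", tolower(cl))
    blocks[[nm]] <- length(col_names) + seq_along(s_levels[[cl]])
    levels[[nm]] <- s_levels[[cl]]
    col_names <- c(col_names, paste0(nm, ":", s_levels[[cl]]))
  }
  if (length(d_levels)) {
    blocks$d <- length(col_names) + seq_along(d_levels)
    levels$d <- d_levels
    col_names <- c(col_names, paste0("d:", d_levels))
  }
  if (length(p_levels)) {
    blocks$p <- length(col_names) + seq_along(p_levels)
    levels$p <- p_levels
    col_names <- c(col_names, paste0("p:", p_levels))
  }
  blocks$const <- length(col_names) + 1L
  col_names <- c(col_names, "const")

  n <- nrow(meta)
  p <- length(col_names)
  X <- matrix(0, n, p, dimnames = list(meta$row_id, col_names))
  X[, blocks$const] <- 1
  X[cbind(seq_len(n), blocks$m[match(meta$site_id, all_sites)])] <- 1
  for (cl in names(s_levels)) {
    nm <- paste0("s_", tolower(cl))
    rows <- which(multi & meta$diagnosis == cl &
                    meta$site_id %in% s_levels[[cl]])
    X[cbind(rows, blocks[[nm]][match(meta$site_id[rows], s_levels[[cl]])])] <- 1
  }
  if (length(d_levels)) {
    rows <- which(multi & meta$diagnosis %in% d_levels)
    X[cbind(rows, blocks$d[match(meta$diagnosis[rows], d_levels)])] <- 1
  }
  if (length(p_levels)) {
    rows <- which(trav)
    X[cbind(rows, blocks$p[match(meta$participant_id[rows], p_levels)])] <- 1
  }

  constrained <- setdiff(names(blocks), c("d", "const"))
  C <- matrix(0, length(constrained), p,
              dimnames = list(constrained, col_names))
  for (k in seq_along(constrained)) C[k, blocks[[constrained[k]]]] <- 1

  penalty <- rep(1, p)
  penalty[blocks$const] <- 0

  structure(list(X = X, C = C, blocks = blocks, levels = levels,
                 penalty = penalty),
            class = "bias_design")
}

#' Equality-constrained ridge regression via the KKT system
#'
#' Minimizes `||y - X w||^2 + lambda ||w_pen||^2` subject to `C w = 0` by
#' solving the Karush-Kuhn-Tucker linear system. The intercept is excluded
#' from the penalty by default. With `lambda = 0` on a rank-deficient
#' design, the KKT system is singular and an explicit error advises
#' `lambda > 0`.
#'
#' @param y Numeric response vector (one edge) or n x E matrix (edges as
#'   columns).
#' @param design A `bias_design`, or a plain list with `X`, `C`, `penalty`.
#' @param lambda Non-negative ridge weight.
#' @param penalize_intercept If `TRUE`, the intercept is penalized too.
#' @return List with `coef` (p x E matrix, rownames = design columns),
#'   `residual_variance` (RSS/n per edge), `constraint_residual`
#'   (max |C w|).
#' @export
fit_constrained_ridge <- function(y, design, lambda,
                                  penalize_intercept = FALSE) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  X <- design$X
  C <- design$C
  penalty <- design$penalty
  if (penalize_intercept) penalty[] <- 1
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (nrow(Y) != nrow(X)) stop("response length does not match design",
                               call. = FALSE)
  p <- ncol(X)
  q <- nrow(C)
  H <- crossprod(X) + diag(lambda * penalty, p)
  K <- rbind(cbind(H, t(C)), cbind(C, matrix(0, q, q)))
  rhs <- rbind(crossprod(X, Y), matrix(0, q, ncol(Y)))
  sol <- tryCatch(solve(K, rhs), error = function(e) {
    stop(paste0("KKT system is singular (design rank-deficient); ",
                "use lambda > 0"), call. = FALSE)
  })
  W <- sol[seq_len(p), , drop = FALSE]
  rownames(W) <- colnames(X)
  fitted <- X %*% W
  list(coef = W,
       residual_variance = colMeans((Y - fitted)^2),
       constraint_residual = if (q) max(abs(C %*% W)) else 0)
}

#' Fit the bias decomposition on every edge
#'
#' Assembles the joint design once and solves the constrained ridge problem
#' for all edges against a single factorization, which is identical to
#' fitting edges one at a time.
#'
#' @param dataset Combined multisite + traveling [fc_dataset()].
#' @param lambda Ridge weight (see [select_lambda()]).
#' @param design Optional precomputed `bias_design` for `dataset`.
#' @return Object of class `bias_decomposition`: per-factor matrices
#'   (levels x edges) `measurement`, `sampling_hc`, `sampling_mdd`,
#'   `sampling_scz`, `disorder`, `participant` (absent blocks are `NULL`),
#'   `intercept` and `residual_variance` edge vectors, `lambda`, `levels`,
#'   and `n_edges`.
#' @export
fit_all_edges <- function(dataset, lambda, design = NULL) {
  stopifnot(inherits(dataset, "fc_dataset"))
  if (is.null(design)) design <- assemble_design(dataset)
  fit <- fit_constrained_ridge(dataset$values, design, lambda)
  W <- fit$coef
  pick <- function(block) {
    if (is.null(design$blocks[[block]])) return(NULL)
    m <- W[design$blocks[[block]], , drop = FALSE]
    rownames(m) <- design$levels[[block]]
    m
  }
  structure(list(
    measurement = pick("m"),
    sampling_hc = pick("s_hc"),
    sampling_mdd = pick("s_mdd"),
    sampling_scz = pick("s_scz"),
    disorder = pick("d"),
    participant = pick("p"),
    intercept = as.numeric(W[design$blocks$const, ]),
    residual_variance = fit$residual_variance,
    lambda = lambda,
    levels = design$levels,
    constraint_residual = fit$constraint_residual,
    n_edges = ncol(W)
  ), class = "bias_decomposition")
}

#' @export
print.bias_decomposition <- function(x, ...) {
  blk <- function(m) if (is.null(m)) 0L else nrow(m)
  cat(sprintf(paste0(
    "<bias_decomposition> %d edges, lambda = %g\n",
    "  measurement bias: %d sites; sampling bias HC/MDD/SCZ: %d/%d/%d sites\n",
    "  disorder factors: %d; participant factors: %d\n"),
    x$n_edges, x$lambda, blk(x$measurement), blk(x$sampling_hc),
    blk(x$sampling_mdd), blk(x$sampling_scz), blk(x$disorder),
    blk(x$participant)))
  invisible(x)
}

# mean correlation, across matched sites, between two factor blocks
between_bias_correlation <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) return(NA_real_)
  mean(vapply(shared,
              function(s) stats::cor(a[s, ], b[s, ]),
              numeric(1)))
}

#' Select the ridge weight by minimizing spurious between-bias correlations
#'
#' Without regularization the rank-deficient design induces spurious
#' anticorrelation between measurement bias and HC sampling bias, and
#' spurious correlation between HC sampling bias and the patient sampling
#' biases. For each lambda on the grid the model is refit and the criterion
#' is the absolute mean of the three between-bias correlation families
#' (m vs s_hc, s_hc vs s_mdd, s_hc vs s_scz), each averaged over matched
#' sites; the chosen lambda attains the grid minimum. An optional
#' permutation mode shuffles site labels (within dataset kind) to produce
#' the null criterion curve.
#'
#' @param dataset Combined multisite + traveling [fc_dataset()].
#' @param grid Non-empty vector of candidate lambdas (default 0:20).
#' @param with_permutation Also compute the criterion on site-permuted data.
#' @param seed Seed for the permutation.
#' @return List of class `lambda_search`: `grid`, `criterion`, `lambda`
#'   (chosen), and optionally `permutation_criterion`.
#' @export
select_lambda <- function(dataset, grid = 0:20, with_permutation = FALSE,
                          seed = NULL) {
  if (length(grid) == 0) stop("lambda grid is empty", call. = FALSE)
  if (any(grid < 0)) stop("lambda grid values must be >= 0", call. = FALSE)
  criterion_curve <- function(ds) {
    design <- assemble_design(ds)
    vapply(grid, function(l) {
      dec <- tryCatch(fit_all_edges(ds, l, design = design),
                      error = function(e) NULL)
      if (is.null(dec)) return(NA_real_)
      fams <- c(
        between_bias_correlation(dec$measurement, dec$sampling_hc),
        between_bias_correlation(dec$sampling_hc, dec$sampling_mdd),
        between_bias_correlation(dec$sampling_hc, dec$sampling_scz))
      abs(mean(fams, na.rm = TRUE))
    }, numeric(1))
  }
  criterion <- criterion_curve(dataset)
  if (all(is.na(criterion))) stop("criterion undefined on the whole grid",
                                  call. = FALSE)
  chosen <- grid[which.min(criterion)]
  out <- list(grid = grid, criterion = criterion, lambda = chosen)
  if (with_permutation) {
    if (!is.null(seed)) set.seed(seed)
    perm <- dataset
    for (kind in c("multisite", "traveling")) {
      rows <- perm$meta$dataset_kind == kind
      perm$meta$site_id[rows] <- sample(perm$meta$site_id[rows])
    }
    out$permutation_criterion <- criterion_curve(perm)
  }
  class(out) <- "lambda_search"
  out
}

#' Check the sum-to-zero constraints of a decomposition
#'
#' @param decomposition A `bias_decomposition`.
#' @param tol Tolerance on the per-edge block sums.
#' @return `TRUE` invisibly; errors if a constraint is violated.
#' @export
check_constraints <- function(decomposition, tol = 1e-6) {
  for (block in c("measurement", "sampling_hc", "sampling_mdd",
                  "sampling_scz", "participant")) {
    m <- decomposition[[block]]
    if (is.null(m)) next
    worst <- max(abs(colSums(m)))
    if (worst > tol) {
      stop(sprintf("block %s violates sum-to-zero (max |sum| = %g)",
                   block, worst), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a bias decomposition to a directory of TSV files
#'
#' One TSV per factor block (levels x edges) plus `intercept.tsv`,
#' `residual_variance.tsv`, and a JSON manifest recording lambda and the
#' constraint residual.
#'
#' @param decomposition A `bias_decomposition`.
#' @param dir Output directory (created if needed).
#' @export
write_decomposition <- function(decomposition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- c("measurement", "sampling_hc", "sampling_mdd", "sampling_scz",
              "disorder", "participant")
  for (block in blocks) {
    m <- decomposition[[block]]
    if (is.null(m)) next
    out <- data.frame(level = rownames(m), m, check.names = FALSE)
    utils::write.table(out, file.path(dir, paste0(block, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(intercept = decomposition$intercept,
               residual_variance = decomposition$residual_variance),
    file.path(dir, "edge_terms.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(lambda = decomposition$lambda,
         n_edges = decomposition$n_edges,
         constraint_residual = decomposition$constraint_residual,
         levels = decomposition$levels),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(decomposition)
}
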