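#' Edge index for the lower triangle of a connectivity matrix
#'
#' Enumerates every unordered pair of atlas nodes exactly once, following the
#' lower triangular part of the K x K connectivity matrix in column-major
#' order: pairs (i, j) with j < i, sorted by j then i. For the 268-node atlas
#' this yields the 35,778 connectivity values used throughout.
#'
#' @param n_nodes Number of atlas nodes (>= 2).
#' @return An object of class `edge_index`: a list with `n_nodes`, integer
#'   vectors `i` and `j` (1-based node indices, `j < i`), `n_edges`, and
#'   `labels` of the form `"n<i>_n<j>"`.
#' @examples
#' idx <- build_edge_index(268)
#' idx$n_edges  # 35778
#' @export
build_edge_index <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || is.na(n_nodes) ||
      n_nodes < 2 || n_nodes != round(n_nodes)) {
    stop("invalid atlas: 'n_nodes' must be a single integer >= 2", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  # column-major lower triangle: for each column j, rows i = j+1 .. K
  j <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  i <- sequence((n_nodes - 1L):1L) + j
  structure(
    list(
      n_nodes = n_nodes,
      i = i,
      j = j,
      n_edges = length(i),
      labels = paste0("n", i, "_n", j)
    ),
    class = "edge_index"
  )
}

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("<edge_index> %d nodes, %d edges (lower triangle, column-major)\n",
              x$n_nodes, x$n_edges))
  invisible(x)
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the lower-triangular entries of a symmetric matrix in the fixed
#' ordering of an [build_edge_index()] object. The diagonal is ignored.
#'
#' @param sym_matrix K x K numeric matrix, symmetric within `tol`.
#' @param edge_index An `edge_index` with `n_nodes == K`.
#' @param tol Symmetry tolerance (max absolute difference).
#' @return Numeric edge vector of length `edge_index$n_edges`.
#' @export
vectorize_matrix <- function(sym_matrix, edge_index, tol = 1e-8) {
  stopifnot(inherits(edge_index, "edge_index"))
  if (!is.matrix(sym_matrix) || nrow(sym_matrix) != ncol(sym_matrix)) {
    stop("'sym_matrix' must be a square matrix", call. = FALSE)
  }
  if (nrow(sym_matrix) != edge_index$n_nodes) {
    stop(sprintf("matrix has %d nodes but edge_index expects %d",
                 nrow(sym_matrix), edge_index$n_nodes), call. = FALSE)
  }
  if (max(abs(sym_matrix - t(sym_matrix))) > tol) {
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  }
  sym_matrix[cbind(edge_index$i, edge_index$j)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_matrix()] off the diagonal; the diagonal is filled
#' with `diag_value`.
#'
#' @param edge_values Numeric vector following the edge-index ordering.
#' @param edge_index An `edge_index`.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return K x K symmetric numeric matrix.
#' @export
devectorize_matrix <- function(edge_values, edge_index, diag_value = 0) {
  stopifnot(inherits(edge_index, "edge_index"))
  if (length(edge_values) != edge_index$n_edges) {
    stop(sprintf("edge vector has length %d, expected %d",
                 length(edge_values), edge_index$n_edges), call. = FALSE)
  }
  K <- edge_index$n_nodes
  m <- matrix(diag_value, K, K)
  m[cbind(edge_index$i, edge_index$j)] <- edge_values
  m[cbind(edge_index$j, edge_index$i)] <- edge_values
  m
}

#' Read an atlas node table
#'
#' TSV with columns `node_id`, optional `node_name`, and optional MNI
#' coordinates `x`, `y`, `z`.
#'
#' @param path Path to the atlas TSV file.
#' @return A list of class `atlas_spec` with `node_ids`, `node_names`,
#'   `node_coords` (matrix or NULL), and `n_nodes`.
#' @export
read_atlas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"node_id" %in% names(tab)) {
    stop("atlas file must have a 'node_id' column", call. = FALSE)
  }
  ids <- as.character(tab$node_id)
  if (anyDuplicated(ids)) stop("atlas node ids must be unique", call. = FALSE)
  if (length(ids) < 2) stop("invalid atlas: need at least 2 nodes", call. = FALSE)
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(tab))) {
    coords <- as.matrix(tab[, c("x", "y", "z")])
  }
  structure(
    list(
      node_ids = ids,
      node_names = if ("node_name" %in% names(tab)) as.character(tab$node_name) else ids,
      node_coords = coords,
      n_nodes = length(ids)
    ),
    class = "atlas_spec"
  )
}
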