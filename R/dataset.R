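#' Connectivity dataset container
#'
#' Bundles a subject/session-by-edge matrix of Fisher-z functional
#' connectivity values with per-row metadata and the edge index describing
#' the column ordering. Rows of a multisite dataset are one scan per
#' participant; rows of a traveling-subject dataset are one scan session.
#'
#' @param values Numeric matrix, rows = scans, columns = edges.
#' @param meta `data.frame` with columns `row_id`, `participant_id`,
#'   `site_id`, `diagnosis` (one of `r paste(DIAGNOSIS_LEVELS, collapse = ", ")`),
#'   `dataset_kind` (`"multisite"` or `"traveling"`), `session_id` (optional).
#' @param edge_index An [build_edge_index()] object whose `n_edges` matches
#'   `ncol(values)`.
#' @return An object of class `fc_dataset`.
#' @export
fc_dataset <- function(values, meta, edge_index) {
  stopifnot(inherits(edge_index, "edge_index"))
  values <- as.matrix(values)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("row_id", "participant_id", "site_id", "diagnosis", "dataset_kind")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"session_id" %in% names(meta)) meta$session_id <- NA_character_
  for (col in c(required, "session_id")) meta[[col]] <- as.character(meta[[col]])

  if (nrow(values) != nrow(meta)) {
    stop(sprintf("value matrix has %d rows but metadata has %d",
                 nrow(values), nrow(meta)), call. = FALSE)
  }
  if (ncol(values) != edge_index$n_edges) {
    stop(sprintf("value matrix has %d columns but edge index has %d edges",
                 ncol(values), edge_index$n_edges), call. = FALSE)
  }
  dup <- meta$row_id[duplicated(meta$row_id)]
  if (length(dup)) {
    stop("duplicate row_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rows <- meta$row_id[unique(((bad - 1L) %% nrow(values)) + 1L)]
    stop("non-finite connectivity values in rows: ",
         paste(utils::head(rows, 10), collapse = ", "), call. = FALSE)
  }
  unknown <- !(meta$diagnosis %in% DIAGNOSIS_LEVELS)
  if (any(unknown)) {
    warning("unknown diagnosis labels mapped to OTHER: ",
            paste(unique(meta$diagnosis[unknown]), collapse = ", "), call. = FALSE)
    meta$diagnosis[unknown] <- "OTHER"
  }
  if (!all(meta$dataset_kind %in% c("multisite", "traveling"))) {
    stop("dataset_kind must be 'multisite' or 'traveling'", call. = FALSE)
  }
  trav_bad <- meta$dataset_kind == "traveling" & meta$diagnosis != "HC"
  if (any(trav_bad)) {
    stop("traveling rows must have diagnosis HC; offending rows: ",
         paste(utils::head(meta$row_id[trav_bad], 10), collapse = ", "),
         call. = FALSE)
  }
  rownames(values) <- meta$row_id
  colnames(values) <- edge_index$labels
  structure(list(values = values, meta = meta, edge_index = edge_index),
            class = "fc_dataset")
}

#' Diagnosis labels recognized by the data model
#' @export
DIAGNOSIS_LEVELS <- c("HC", "MDD", "SCZ", "ASD", "OTHER")

#' @export
print.fc_dataset <- function(x, ...) {
  kinds <- table(x$meta$dataset_kind)
  cat(sprintf("<fc_dataset> %d rows x %d edges (%d nodes); sites: %d; %s\n",
              nrow(x$values), x$edge_index$n_edges, x$edge_index$n_nodes,
              length(unique(x$meta$site_id)),
              paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}

#' Number of rows of an fc_dataset
#' @param x An `fc_dataset`.
#' @export
n_scans <- function(x) nrow(x$values)

#' Subset an fc_dataset by row
#' @param x An `fc_dataset`.
#' @param rows Logical or integer row selector.
#' @return An `fc_dataset` restricted to the selected rows.
#' @export
subset_rows <- function(x, rows) {
  stopifnot(inherits(x, "fc_dataset"))
  fc_dataset(x$values[rows, , drop = FALSE], x$meta[rows, , drop = FALSE],
             x$edge_index)
}

#' Concatenate fc_datasets sharing an edge index
#' @param ... `fc_dataset` objects with identical edge indexing.
#' @return A combined `fc_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1, all(vapply(ds, inherits, TRUE, "fc_dataset")))
  n_edges <- vapply(ds, function(d) d$edge_index$n_edges, 1L)
  if (length(unique(n_edges)) != 1) {
    stop("datasets have different edge counts", call. = FALSE)
  }
  fc_dataset(do.call(rbind, lapply(ds, `[[`, "values")),
             do.call(rbind, lapply(ds, `[[`, "meta")),
             ds[[1]]$edge_index)
}

#' Read a connectivity dataset from values + metadata TSV files
#'
#' The values file is a TSV whose first column is `row_id` and remaining
#' columns are edge labels `n<i>_n<j>`; the metadata file is a TSV with
#' columns `row_id`, `participant_id`, `site_id`, `diagnosis`,
#' `dataset_kind`, and optionally `session_id`. Rows are matched by
#' `row_id`; a mismatch is an error naming the offending ids.
#'
#' @param values_path Path to the values TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param apply_fisher_z If `TRUE`, values are raw correlations and `atanh`
#'   is applied on load (with the standard cap near |r| = 1).
#' @return An `fc_dataset`.
#' @export
read_dataset <- function(values_path, metadata_path, apply_fisher_z = FALSE) {
  vals <- utils::read.delim(values_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (names(vals)[1] != "row_id") {
    stop("values file must have 'row_id' as its first column", call. = FALSE)
  }
  row_ids <- as.character(vals$row_id)
  mat <- as.matrix(vals[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  meta$row_id <- as.character(meta$row_id)
  only_vals <- setdiff(row_ids, meta$row_id)
  only_meta <- setdiff(meta$row_id, row_ids)
  if (length(only_vals) || length(only_meta)) {
    stop("row_id mismatch between files; missing from metadata: ",
         paste(utils::head(only_vals, 5), collapse = ", "),
         "; missing from values: ",
         paste(utils::head(only_meta, 5), collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(row_ids, meta$row_id), , drop = FALSE]
  if (apply_fisher_z) mat <- fisher_z(mat)
  edge_index <- edge_index_from_labels(colnames(mat))
  fc_dataset(mat, meta, edge_index)
}

#' Reconstruct an edge index from "n<i>_n<j>" column labels
#' @param labels Character vector of edge labels.
#' @return An `edge_index` whose ordering matches the labels.
#' @keywords internal
edge_index_from_labels <- function(labels) {
  parts <- regmatches(labels, regexec("^n([0-9]+)_n([0-9]+)$", labels))
  ok <- lengths(parts) == 3L
  if (!all(ok)) {
    stop("unrecognized edge labels: ",
         paste(utils::head(labels[!ok], 5), collapse = ", "), call. = FALSE)
  }
  i <- as.integer(vapply(parts, `[`, "", 2L))
  j <- as.integer(vapply(parts, `[`, "", 3L))
  idx <- build_edge_index(max(i, j))
  if (!identical(idx$labels, labels)) {
    # not the full lower triangle of a square atlas: keep as given
    idx$i <- i
    idx$j <- j
    idx$n_edges <- length(i)
    idx$labels <- labels
  }
  idx
}

#' Write a connectivity dataset to values + metadata TSV files
#' @param dataset An `fc_dataset`.
#' @param values_path Output path for the values TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @export
write_dataset <- function(dataset, values_path, metadata_path) {
  stopifnot(inherits(dataset, "fc_dataset"))
  out <- data.frame(row_id = dataset$meta$row_id, dataset$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Fisher z transform with a finite cap at |r| = 1
#'
#' `atanh(r)` after clamping `|r|` to `1 - 1e-7`, keeping degenerate perfect
#' correlations finite.
#'
#' @param r Correlation values.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  cap <- 1 - 1e-7
  atanh(pmin(pmax(r, -cap), cap))
}
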