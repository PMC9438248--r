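#' Construct a per-batch metabolomics dataset
#'
#' A batch holds raw nonnegative ion counts for the metabolite features it
#' measures, as a samples x features matrix. Two kinds of missingness are
#' distinguished: an entry can be *left-censored* (the feature is measured in
#' the batch but this sample's level fell below the detection threshold), and
#' a feature can be entirely *unmeasured* in the batch (such features simply
#' do not appear among the columns). Censored entries are stored as `NA` in
#' `values` and flagged in `censored`.
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   row and column names. Entries must be nonnegative; `NA` marks a
#'   left-censored entry.
#' @param batch_id Single string naming the batch.
#' @param censored Optional logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return An object of class `raw_dataset`.
#' @export
raw_dataset <- function(values, batch_id = "batch1", censored = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have sample row names and feature column names")
  }
  censored <- censored %||% is.na(values)
  if (!identical(dim(censored), dim(values))) {
    abort("`censored` must have the same shape as `values`")
  }
  values[censored] <- NA_real_
  ds <- structure(
    list(batch_id = as.character(batch_id),
         values = values,
         censored = censored),
    class = "raw_dataset"
  )
  validate_raw_dataset(ds)
}

validate_raw_dataset <- function(ds) {
  v <- ds$values
  if (anyDuplicated(rownames(v))) {
    abort(sprintf("duplicate sample ids in batch '%s': %s", ds$batch_id,
                  paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(v))) {
    abort(sprintf("duplicate feature names in batch '%s': %s", ds$batch_id,
                  paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  }
  bad <- which(!is.na(v) & v < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("negative value at sample '%s', feature '%s' in batch '%s'",
                  rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]], ds$batch_id))
  }
  if (any(is.na(v) & !ds$censored)) {
    abort("NA entries must be flagged censored")
  }
  ds
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<raw_dataset '%s'> %d samples x %d features, %d censored (%.1f%%)\n",
              x$batch_id, nrow(x$values), ncol(x$values), sum(x$censored),
              100 * mean(x$censored)))
  invisible(x)
}

#' @rdname raw_dataset
#' @param x Object to query.
#' @export
measured_features <- function(x) colnames(x$values)

#' @rdname raw_dataset
#' @export
sample_ids <- function(x) rownames(x$values)

#' Aggregate rank-transformed batches into one matrix
#'
#' Stacks rank-transformed batches into a single samples x features matrix
#' over the union of (harmonized) feature names. A cell is *observed* exactly
#' when the feature is measured in that sample's batch; unmeasured cells are
#' `NA` and carry `observed = FALSE`. Censored entries are observed at their
#' tied sub-minimum rank. If a sample id occurs in more than one batch, ids
#' are disambiguated as `batch_id:sample_id` (with a message), never merged.
#'
#' @param datasets A list of `ranked_dataset` objects (see
#'   [rank_transform()]); a single object is accepted.
#' @return An `aggregate_matrix`: list with `values` (m x n, `NA` where
#'   unobserved), `observed` (logical m x n), `batch` (length-m batch label
#'   per sample) and matrix dimnames carrying sample/feature ids.
#' @export
aggregate_ranked <- function(datasets) {
  if (inherits(datasets, "ranked_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) abort("need at least one dataset to aggregate")
  ok <- vapply(datasets, inherits, logical(1), "ranked_dataset")
  if (!all(ok)) abort("all datasets must be rank-transformed first")

  ids <- unlist(lapply(datasets, function(d) rownames(d$values)))
  namespaced <- anyDuplicated(ids) > 0
  if (namespaced) {
    message("duplicate sample ids across batches; prefixing with batch id")
  }
  feats <- unique(unlist(lapply(datasets, function(d) colnames(d$values))))
  rows <- lapply(datasets, function(d) {
    rn <- rownames(d$values)
    if (namespaced) rn <- paste(d$batch_id, rn, sep = ":")
    rn
  })
  m <- sum(lengths(rows))
  values <- matrix(NA_real_, m, length(feats),
                   dimnames = list(unlist(rows), feats))
  observed <- matrix(FALSE, m, length(feats),
                     dimnames = dimnames(values))
  batch <- character(m)
  at <- 0L
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    idx <- at + seq_len(nrow(d$values))
    values[idx, colnames(d$values)] <- d$values
    observed[idx, colnames(d$values)] <- TRUE
    batch[idx] <- d$batch_id
    at <- at + nrow(d$values)
  }
  if (anyDuplicated(rownames(values))) abort("duplicate sample ids within a batch")
  message(sprintf("aggregate: %d samples x %d features, %.1f%% unobserved",
                  m, length(feats), 100 * mean(!observed)))
  structure(list(values = values, observed = observed, batch = batch),
            class = "aggregate_matrix")
}

#' @export
print.aggregate_matrix <- function(x, ...) {
  cat(sprintf("<aggregate_matrix> %d samples x %d features, %d batches, %.1f%% unobserved\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              100 * mean(!x$observed)))
  invisible(x)
}

as_aggregate <- function(x) {
  if (inherits(x, "aggregate_matrix")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    return(structure(list(values = x, observed = !is.na(x),
                          batch = rep("batch1", nrow(x))),
                     class = "aggregate_matrix"))
  }
  abort("expected an aggregate_matrix or a plain matrix")
}
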