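#' Features eligible for dataset-wise cross-validation
#'
#' With several batches, a feature of batch i can only be scored if masking
#' it still leaves information to impute it from, i.e. it is measured in at
#' least one other batch. With a single batch every feature is eligible
#' (within-set CV masks sample subsets instead, see [cv_select_k()]).
#'
#' @param datasets List of datasets (`raw_dataset`/`ranked_dataset`) or an
#'   `aggregate_matrix`.
#' @return Named list: per batch, the character vector of eligible features.
#' @export
eligible_features <- function(datasets) {
  feats <- batch_feature_sets(datasets)
  if (length(feats) == 1) return(feats)
  lapply(seq_along(feats), function(i) {
    others <- unique(unlist(feats[-i]))
    feats[[i]][feats[[i]] %in% others]
  }) |> setNames(names(feats))
}

batch_feature_sets <- function(datasets) {
  if (inherits(datasets, "aggregate_matrix")) {
    ub <- unique(datasets$batch)
    return(setNames(lapply(ub, function(b) {
      idx <- datasets$batch == b
      colnames(datasets$values)[colSums(datasets$observed[idx, , drop = FALSE]) > 0]
    }), ub))
  }
  if (inherits(datasets, "raw_dataset") || inherits(datasets, "ranked_dataset")) {
    datasets <- list(datasets)
  }
  setNames(lapply(datasets, function(d) colnames(d$values)),
           vapply(datasets, function(d) d$batch_id, character(1)))
}

#' Assign eligible features to cross-validation folds
#'
#' Partitions each batch's eligible features into `v` near-equal folds,
#' randomized independently per batch so that a feature shared between
#' batches usually sits in different folds in different batches (keeping it
#' observed somewhere when its fold is masked).
#'
#' @param eligible Named list of per-batch eligible feature vectors (from
#'   [eligible_features()]).
#' @param v Number of folds (>= 2).
#' @param seed Seed; the assignment is deterministic given `(eligible, v, seed)`.
#' @return A `fold_assignment`: per batch, an integer fold label per feature.
#' @export
assign_folds <- function(eligible, v, seed = 1L) {
  if (!is.numeric(v) || v < 2) abort("`v` must be at least 2")
  v <- as.integer(v)
  folds <- lapply(seq_along(eligible), function(i) {
    feats <- eligible[[i]]
    if (length(feats) < v) {
      warn(sprintf("batch '%s' has %d eligible features for %d folds; folds will be uneven",
                   names(eligible)[i], length(feats), v))
    }
    lab <- rep(seq_len(v), length.out = length(feats))
    with_seed(derive_seed(seed, "folds", i), {
      setNames(sample(lab), sample(feats))
    })
  })
  structure(setNames(folds, names(eligible)), class = "fold_assignment", v = v)
}

#' Select the number of embedding dimensions by v-fold cross-validation
#'
#' For each candidate `k` and each fold: the fold's features are masked
#' (set unobserved) in each batch where the fold assignment places them, the
#' masked matrix is factorized at `k`, the reconstruction is re-ranked, and
#' the mean absolute error (MAE) between the true and imputed ranks over the
#' masked cells scores the fold. Fold scores are averaged per `k` (simple
#' mean) and the `k` with the lowest MAE wins; ties go to the smallest `k`.
#'
#' With a single batch, fold features are instead masked in a random half of
#' the samples (masking a whole feature in its only batch would leave
#' nothing to learn its embedding from). With several batches, a feature
#' that happens to land in the same fold in every batch measuring it would
#' leave an all-unobserved column; such columns are dropped from that fold's
#' fit and excluded from its MAE (with a warning). A fold is skipped
#' entirely only if masking empties a sample's row.
#'
#' @param datasets Datasets (raw, list of raw) or an `aggregate_matrix` of
#'   ranks; raw input is normalized and rank-transformed first.
#' @param k_grid Integer vector of candidate dimensions.
#' @param v Number of folds (default 10).
#' @param seed Seed for fold assignment and NMF initialization.
#' @param normalization Passed to the preprocessing of raw input.
#' @param ... Passed to [fit_nmf_masked()].
#' @return A `mirth_cv` object with `results` (tibble: k, mae, n_folds),
#'   `k_opt`, `v`, `seed`, and the fold assignment.
#' @export
cv_select_k <- function(datasets, k_grid, v = 10L, seed = 1L,
                        normalization = c("tic", "pqn", "none"), ...) {
  normalization <- match.arg(normalization)
  if (length(k_grid) < 1 || any(k_grid < 1)) abort("`k_grid` must be positive integers")
  k_grid <- sort(unique(as.integer(k_grid)))
  agg <- if (inherits(datasets, "aggregate_matrix")) {
    datasets
  } else {
    if (inherits(datasets, "raw_dataset")) datasets <- list(datasets)
    aggregate_ranked(lapply(datasets, function(d) {
      rank_transform(normalize_dataset(d, method = normalization))
    }))
  }
  single_batch <- length(unique(agg$batch)) == 1
  elig <- eligible_features(agg)
  folds <- assign_folds(elig, v = v, seed = derive_seed(seed, "cv-folds"))
  v <- as.integer(v)

  # Per fold: the logical mask of cells to hide
  fold_masks <- lapply(seq_len(v), function(f) {
    mask <- matrix(FALSE, nrow(agg$values), ncol(agg$values),
                   dimnames = dimnames(agg$values))
    for (b in names(folds)) {
      fb <- names(folds[[b]])[folds[[b]] == f]
      if (length(fb) == 0) next
      rows <- which(agg$batch == b)
      if (single_batch) {
        rows <- with_seed(derive_seed(seed, "cv-rows", f),
                          sort(sample(rows, ceiling(length(rows) / 2))))
      }
      mask[rows, fb] <- TRUE
    }
    mask & agg$observed
  })

  scores <- matrix(NA_real_, v, length(k_grid))
  for (f in seq_len(v)) {
    mask <- fold_masks[[f]]
    if (!any(mask)) next
    obs_train <- agg$observed & !mask
    drop_cols <- colSums(obs_train) == 0
    if (any(drop_cols)) {
      warn(sprintf("fold %d: %d feature(s) left with no observed entries; dropped from this fold",
                   f, sum(drop_cols)))
    }
    keep <- !drop_cols
    if (any(rowSums(obs_train[, keep, drop = FALSE]) == 0)) {
      warn(sprintf("fold %d leaves a sample with no observed entries; fold skipped", f))
      next
    }
    train <- structure(list(values = ifelse(obs_train, agg$values, NA_real_)[, keep, drop = FALSE],
                            observed = obs_train[, keep, drop = FALSE],
                            batch = agg$batch),
                       class = "aggregate_matrix")
    mk <- mask[, keep, drop = FALSE]
    truth <- agg$values[, keep, drop = FALSE]
    for (ki in seq_along(k_grid)) {
      fit <- fit_nmf_masked(train, k = k_grid[ki],
                            seed = derive_seed(seed, "cv-fit", f * 1000L + ki), ...)
      imp <- rerank(reconstruct(fit), batch = agg$batch)
      scores[f, ki] <- mean(abs(imp[mk] - truth[mk]))
    }
  }
  ok_folds <- rowSums(!is.na(scores)) > 0
  if (!any(ok_folds)) abort("no usable cross-validation folds")
  mae <- colMeans(scores[ok_folds, , drop = FALSE])
  results <- tibble::tibble(k = k_grid, mae = mae, n_folds = sum(ok_folds))
  structure(
    list(results = results, k_opt = k_grid[which.min(mae)], v = v,
         seed = as.integer(seed), folds = folds,
         fold_scores = scores),
    class = "mirth_cv"
  )
}

#' @export
print.mirth_cv <- function(x, ...) {
  cat(sprintf("<mirth_cv> k_opt = %d over grid [%d..%d], %d folds\n",
              x$k_opt, min(x$results$k), max(x$results$k), x$v))
  invisible(x)
}
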