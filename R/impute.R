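#' Impute unmeasured metabolite ranks across batches
#'
#' The full pipeline: per-batch normalization, censoring-aware rank
#' transformation, aggregation over the union of features, masked NMF at `k`
#' embedding dimensions (or `k = "auto"` for cross-validated selection), and
#' re-ranking of the dense reconstruction. The result contains a rank value
#' in (0,1) for every cell, including features entirely unmeasured in a
#' sample's batch; the provenance mask records which cells were observed in
#' the input.
#'
#' @param datasets A list of [raw_dataset()] objects (or a single one), or a
#'   pre-built `aggregate_matrix` of ranks (in which case normalization and
#'   ranking are skipped).
#' @param k Embedding dimensions, or `"auto"` to pick by [cv_select_k()].
#' @param normalization `"tic"` (default), `"pqn"`, or `"none"`.
#' @param seed Seed controlling initialization (and CV when `k = "auto"`).
#' @param rerank_per_batch Re-rank the reconstruction within each batch
#'   (default) or globally.
#' @param ... Passed to [fit_nmf_masked()] (`backend`, `max_iter`, `tol`,
#'   `n_restarts`) and, when `k = "auto"`, to [cv_select_k()].
#' @param k_grid,v Grid and fold count for `k = "auto"`.
#' @return A `mirth_imputed` object: `values` (imputed ranks, no missing
#'   entries), `observed` (provenance mask), `input_ranks` (the observed rank
#'   matrix), `batch`, `model` (the fitted `mirth_nmf`), and `cv` (a
#'   `mirth_cv`, when `k = "auto"`).
#' @export
mirth_impute <- function(datasets, k = "auto", normalization = c("tic", "pqn", "none"),
                         seed = 1L, rerank_per_batch = TRUE, k_grid = NULL,
                         v = 10L, ...) {
  normalization <- match.arg(normalization)
  if (inherits(datasets, "raw_dataset")) datasets <- list(datasets)
  if (inherits(datasets, "aggregate_matrix")) {
    agg <- datasets
  } else {
    if (length(datasets) == 0) abort("empty dataset list")
    ranked <- lapply(datasets, function(d) {
      rank_transform(normalize_dataset(d, method = normalization))
    })
    agg <- aggregate_ranked(ranked)
  }

  dots <- list(...)
  fit_args <- dots[names(dots) %in% c("backend", "max_iter", "tol", "n_restarts")]
  cv <- NULL
  if (identical(k, "auto")) {
    k_grid <- k_grid %||% seq_len(min(20L, nrow(agg$values) - 1L, ncol(agg$values) - 1L))
    cv <- do.call(cv_select_k,
                  c(list(agg, k_grid = k_grid, v = v,
                         seed = derive_seed(seed, "cv")), fit_args))
    k <- cv$k_opt
  }
  model <- do.call(fit_nmf_masked,
                   c(list(agg, k = k, seed = derive_seed(seed, "fit")), fit_args))
  x_hat <- reconstruct(model)
  imputed <- rerank(x_hat, batch = agg$batch, per_batch = rerank_per_batch)
  structure(
    list(values = imputed, observed = agg$observed, input_ranks = agg$values,
         batch = agg$batch, model = model, cv = cv),
    class = "mirth_imputed"
  )
}

#' @export
print.mirth_imputed <- function(x, ...) {
  cat(sprintf("<mirth_imputed> %d samples x %d features (k = %d); %.1f%% of cells imputed\n",
              nrow(x$values), ncol(x$values), x$model$k, 100 * mean(!x$observed)))
  invisible(x)
}

#' Imputed ranks as a long tibble
#'
#' @param x A `mirth_imputed` object.
#' @param ... Unused.
#' @return A tibble with one row per cell: `sample_id`, `feature`, `batch`,
#'   `rank` (imputed), `input_rank` (`NA` where unmeasured), and `observed`.
#' @export
imputed_tbl <- function(x, ...) {
  stopifnot(inherits(x, "mirth_imputed"))
  tibble::tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    feature = rep(colnames(x$values), each = nrow(x$values)),
    batch = rep(x$batch, times = ncol(x$values)),
    rank = as.vector(x$values),
    input_rank = as.vector(ifelse(x$observed, x$input_ranks, NA_real_)),
    observed = as.vector(x$observed)
  )
}
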