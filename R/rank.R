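#' Censoring-aware rank transformation onto (0, 1)
#'
#' Maps each feature's values, within a batch, to normalized ranks. For an
#' uncensored entry the rank is
#' \deqn{\mathrm{rank}(d_{ij}) = \frac{1 + \sum_{i'} 1[d_{ij} > d_{i'j}]}{1 + N_{total}}}
#' counting strictly-smaller entries over all samples of the feature (ties
#' therefore share the minimum-based rank, and every censored entry counts as
#' smaller than every uncensored one). All left-censored entries of a feature
#' are tied at
#' \deqn{\frac{0.5 (1 + N_{censored})}{1 + N_{total}}}
#' halfway between zero and the smallest uncensored rank. A feature with no
#' censoring is thus mapped uniformly onto (0,1); because any strictly
#' monotone batch distortion preserves order, ranks are invariant to
#' shape-and-scale batch effects of the form \eqn{Y = f(\alpha Y^* + \beta)}.
#'
#' @param ds A `raw_dataset` or `normalized_dataset` (normalization does not
#'   change order within a feature, so ranking commutes with it; it is kept
#'   in the pipeline to mirror the standard preprocessing).
#' @return A `ranked_dataset`: values in (0,1), the censored mask, and
#'   per-feature counts `n_total` and `n_censored`.
#' @export
rank_transform <- function(ds) {
  v <- ds$values
  cens <- ds$censored
  n <- nrow(v)
  out <- v
  n_cens <- integer(ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    cj <- cens[, j]
    c_n <- sum(cj)
    n_cens[j] <- c_n
    # uncensored: 1 + (# censored) + (# strictly smaller uncensored)
    if (any(!cj)) {
      r <- rank(x[!cj], ties.method = "min")
      out[!cj, j] <- (c_n + r) / (1 + n)
    }
    out[cj, j] <- 0.5 * (1 + c_n) / (1 + n)
  }
  structure(
    list(batch_id = ds$batch_id, values = out, censored = cens,
         n_total = setNames(rep(n, ncol(v)), colnames(v)),
         n_censored = setNames(n_cens, colnames(v))),
    class = "ranked_dataset"
  )
}

#' @export
print.ranked_dataset <- function(x, ...) {
  cat(sprintf("<ranked_dataset '%s'> %d samples x %d features\n",
              x$batch_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Re-rank a dense reconstruction onto (0, 1)
#'
#' After factorization the product `W %*% H` is dense but no longer a rank
#' matrix; each feature column is re-ranked so measurements are again mapped
#' uniformly between 0 and 1. Ranking is done per feature within each batch
#' (matching the per-batch input transform); set `per_batch = FALSE` to rank
#' each column globally across the aggregate instead.
#'
#' @param x_hat Numeric m x n matrix with no missing entries.
#' @param batch Length-m batch label per row (recycled to a single batch if
#'   omitted).
#' @param per_batch Rank within batches (default) or globally.
#' @return Matrix of the same shape with values in (0,1); idempotent.
#' @export
rerank <- function(x_hat, batch = NULL, per_batch = TRUE) {
  if (anyNA(x_hat)) abort("reconstruction must have no missing entries")
  batch <- batch %||% rep("batch1", nrow(x_hat))
  if (!per_batch) batch <- rep("all", nrow(x_hat))
  out <- x_hat
  for (b in unique(batch)) {
    idx <- which(batch == b)
    n <- length(idx)
    out[idx, ] <- apply(x_hat[idx, , drop = FALSE], 2,
                        function(x) rank(x, ties.method = "min") / (n + 1))
  }
  out
}
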