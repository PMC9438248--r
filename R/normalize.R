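#' Total ion count (TIC) normalization
#'
#' Divides each sample's ion counts by its total ion count. Left-censored
#' entries, whose magnitude is only known to lie below the detection
#' threshold, contribute half the minimum observed value to the total:
#' for sample i,
#' \deqn{f_i = \sum_j d_{ij} + 0.5 \cdot \min(D) \cdot N_{censored,i}}
#' where the sum runs over the sample's uncensored entries and \eqn{\min(D)}
#' is the smallest uncensored value in the batch (set
#' `minimum = "sample"` to use each sample's own minimum instead).
#'
#' @param ds A [raw_dataset()].
#' @param minimum Scope of the half-minimum term for censored entries:
#'   `"batch"` (default) or `"sample"`.
#' @return A `normalized_dataset`: same shape, with `normalizer` recording
#'   the per-sample divisor.
#' @export
tic_normalize <- function(ds, minimum = c("batch", "sample")) {
  minimum <- match.arg(minimum)
  v <- ds$values
  if (all(is.na(v))) abort(sprintf("batch '%s' has no uncensored value anywhere", ds$batch_id))
  batch_min <- min(v, na.rm = TRUE)
  n_cens <- rowSums(ds$censored)
  half_min <- if (minimum == "batch") {
    rep(batch_min, nrow(v))
  } else {
    mins <- apply(v, 1, function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
    ifelse(is.na(mins), batch_min, mins)
  }
  f <- rowSums(v, na.rm = TRUE) + 0.5 * half_min * n_cens
  if (any(!is.finite(f)) || any(f <= 0)) {
    bad <- rownames(v)[which(!is.finite(f) | f <= 0)[1]]
    abort(sprintf("sample '%s' has a non-positive TIC normalizer", bad))
  }
  out <- ds
  out$values <- v / f
  out$normalizer <- setNames(f, rownames(v))
  class(out) <- c("normalized_dataset", "raw_dataset")
  out
}

#' Probabilistic quotient normalization (PQN)
#'
#' Builds a reference spectrum as the per-feature median over uncensored
#' values, then scales each sample by the median of its entrywise quotients
#' against the reference, over features where both are defined. Censored
#' entries are excluded from both the reference and the quotients.
#'
#' @param ds A [raw_dataset()] with at least two samples.
#' @return A `normalized_dataset`.
#' @export
pqn_normalize <- function(ds) {
  v <- ds$values
  if (nrow(v) < 2) abort("PQN needs at least 2 samples")
  ref <- apply(v, 2, median, na.rm = TRUE)
  f <- vapply(seq_len(nrow(v)), function(i) {
    q <- v[i, ] / ref
    q <- q[is.finite(q)]
    if (length(q) == 0) {
      abort(sprintf("sample '%s' shares no uncensored feature with the reference",
                    rownames(v)[i]))
    }
    median(q)
  }, numeric(1))
  if (any(f <= 0)) abort("non-positive PQN quotient")
  out <- ds
  out$values <- v / f
  out$normalizer <- setNames(f, rownames(v))
  class(out) <- c("normalized_dataset", "raw_dataset")
  out
}

#' @rdname tic_normalize
#' @param method One of `"tic"`, `"pqn"`, `"none"`.
#' @export
normalize_dataset <- function(ds, method = c("tic", "pqn", "none"), ...) {
  method <- match.arg(method)
  switch(method,
         tic = tic_normalize(ds, ...),
         pqn = pqn_normalize(ds),
         none = {
           out <- ds
           out$normalizer <- setNames(rep(1, nrow(ds$values)), rownames(ds$values))
           class(out) <- c("normalized_dataset", "raw_dataset")
           out
         })
}
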