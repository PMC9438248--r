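#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted factor model
#'
#' One row per (dimension, feature) weight of `H`; set `matrix = "W"` for
#' the sample embeddings instead.
#'
#' @param x A `mirth_nmf` object.
#' @param matrix `"H"` (feature embeddings, default) or `"W"`.
#' @param ... Unused.
#' @return A tibble with `dimension`, `feature`/`sample_id`, `weight`.
#' @export
tidy.mirth_nmf <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "H") {
    tibble::tibble(
      dimension = rep(seq_len(x$k), times = ncol(x$H)),
      feature = rep(colnames(x$H), each = x$k),
      weight = as.vector(x$H)
    )
  } else {
    tibble::tibble(
      sample_id = rep(rownames(x$W), times = x$k),
      dimension = rep(seq_len(x$k), each = nrow(x$W)),
      weight = as.vector(x$W)
    )
  }
}

#' @rdname tidy.mirth_nmf
#' @export
glance.mirth_nmf <- function(x, ...) {
  tibble::tibble(k = x$k, final_loss = x$final_loss, converged = x$converged,
                 n_iter = x$n_iter, backend = x$backend, seed = x$seed,
                 n_samples = nrow(x$W), n_features = ncol(x$H))
}

#' Tidy cross-validation results
#'
#' @param x A `mirth_cv` object.
#' @param ... Unused.
#' @return The per-k MAE table as a tibble.
#' @export
tidy.mirth_cv <- function(x, ...) x$results

#' @rdname tidy.mirth_cv
#' @export
glance.mirth_cv <- function(x, ...) {
  tibble::tibble(k_opt = x$k_opt, mae_min = min(x$results$mae), v = x$v,
                 n_k = nrow(x$results), seed = x$seed)
}

#' Tidy benchmark scores
#'
#' @param x A `mirth_benchmark` object.
#' @param ... Unused.
#' @return The per-trial per-feature score tibble.
#' @export
tidy.mirth_benchmark <- function(x, ...) x$scores

#' @rdname tidy.mirth_benchmark
#' @export
glance.mirth_benchmark <- function(x, ...) {
  flags <- classify_well_predicted(x)
  tibble::tibble(design = x$design, trials = x$trials, k = x$k,
                 n_features_scored = nrow(flags),
                 frac_well_predicted = mean(flags$well_predicted),
                 rho_summary = summarize_rho(x$scores$rho[x$scores$scored]))
}
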