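#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_histogram geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot cross-validation error against embedding dimension
#'
#' @param object A `mirth_cv` object.
#' @param ... Unused.
#' @return A ggplot: MAE per k with the selected k marked.
#' @export
autoplot.mirth_cv <- function(object, ...) {
  ggplot(object$results, aes(x = .data$k, y = .data$mae)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_vline(xintercept = object$k_opt, linetype = "dashed", colour = "red") +
    labs(x = "embedding dimensions (k)", y = "cross-validated MAE",
         title = sprintf("k_opt = %d (%d-fold CV)", object$k_opt, object$v)) +
    theme_minimal()
}

#' Plot per-feature imputation performance
#'
#' Features ordered by decreasing summarized correlation, coloured by the
#' well-predicted call.
#'
#' @param object A `mirth_benchmark` object.
#' @param ... Passed to [classify_well_predicted()].
#' @return A ggplot.
#' @export
autoplot.mirth_benchmark <- function(object, ...) {
  flags <- classify_well_predicted(object, ...)
  flags <- flags[order(-flags$rho_summary), ]
  flags$feature <- factor(flags$feature, levels = flags$feature)
  ggplot(flags, aes(x = .data$feature, y = .data$rho_summary,
                    fill = .data$well_predicted)) +
    geom_col() +
    labs(x = NULL, y = "summarized Spearman rho",
         title = sprintf("%s-design imputation performance (%d trials)",
                         object$design, object$trials)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot the weight distribution of a factor model
#'
#' @param object A `mirth_nmf` object.
#' @param ... Unused.
#' @return A ggplot histogram of feature-embedding weights per dimension.
#' @export
autoplot.mirth_nmf <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$weight)) +
    geom_histogram(bins = 30) +
    facet_wrap(~.data$dimension) +
    labs(x = "feature weight", y = "count",
         title = sprintf("feature embedding weights (k = %d)", object$k)) +
    theme_minimal()
}
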