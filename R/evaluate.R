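#' Score one masking trial by per-feature Spearman correlation
#'
#' For each held-out feature, correlates the imputed ranks with the true
#' (pre-masking) ranks over the masked samples only, by Spearman's rho with a
#' two-sided p-value. Observed (unmasked) cells never contribute. Features
#' with fewer than 3 masked samples, or with zero variance in the truth
#' (e.g. all-censored), are returned unscored (`scored = FALSE`).
#'
#' @param truth The unmasked `aggregate_matrix` of true ranks.
#' @param imputed A `mirth_imputed` object (or the imputed rank matrix).
#' @param plan The `mask_plan` that was applied before imputation.
#' @return A tibble: `feature`, `n` (masked samples scored), `rho`, `p`,
#'   `scored`.
#' @export
score_trial <- function(truth, imputed, plan) {
  stopifnot(inherits(plan, "mask_plan"))
  tv <- if (inherits(truth, "aggregate_matrix")) truth$values else truth
  iv <- if (inherits(imputed, "mirth_imputed")) imputed$values else imputed
  stopifnot(identical(dim(tv), dim(iv)))
  feats <- plan$held_features
  purrr::map_dfr(feats, function(f) {
    cells <- plan$mask[, f]
    x <- tv[cells, f]
    y <- iv[cells, f]
    keep <- !is.na(x)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(tibble::tibble(feature = f, n = length(x), rho = NA_real_,
                            p = NA_real_, scored = FALSE))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble::tibble(feature = f, n = length(x), rho = unname(ct$estimate),
                   p = ct$p.value, scored = TRUE)
  })
}

#' Summarize Spearman correlations through Fisher's z
#'
#' Correlations are z-transformed (`atanh`), summarized by the median, and
#' transformed back (`tanh`), so the summary respects the bounded,
#' non-linear scale of rho. Values at +/-1 are clipped to 1 - 1e-12 with a
#' warning.
#'
#' @param rhos Numeric vector of correlations in `[-1, 1]`.
#' @param na_rm Drop `NA` values first.
#' @return The summarized correlation (single number).
#' @export
summarize_rho <- function(rhos, na_rm = TRUE) {
  if (na_rm) rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0) abort("no correlations to summarize")
  if (any(abs(rhos) > 1)) abort("correlations must lie in [-1, 1]")
  if (any(abs(rhos) == 1)) {
    warn("correlation(s) at +/-1 clipped before z-transformation")
    rhos <- pmin(pmax(rhos, -1 + 1e-12), 1 - 1e-12)
  }
  tanh(median(atanh(rhos)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; monotone in the input
#' order of p-values and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run repeated masking trials and collect per-feature scores
#'
#' Repeats a masking design `trials` times with independent seeded draws:
#' mask, impute at `k` dimensions, score ([score_trial()]), and BH-adjust
#' p-values within each trial (across that trial's masked features).
#'
#' @param datasets List of [raw_dataset()] objects or an `aggregate_matrix`.
#' @param design `"within"`, `"across"`, or `"mode"`.
#' @param k Embedding dimensions for each trial's fit.
#' @param trials Number of masking trials (the full-scale benchmark uses
#'   200; scale down for interactive use).
#' @param seed Root seed; trial t uses a derived seed.
#' @param frac_samples,frac_features,target,modes,masked_mode,metabolite_of
#'   Passed to the design's mask constructor.
#' @param normalization,... Passed to preprocessing / [fit_nmf_masked()].
#' @return A `mirth_benchmark`: `scores` (tibble with trial, feature, n,
#'   rho, p, q), the design, and the aggregate's dimensions.
#' @export
run_benchmark <- function(datasets, design = c("within", "across", "mode"),
                          k, trials = 20L, seed = 1L,
                          frac_samples = 0.5, frac_features = 0.1,
                          target = NULL, modes = NULL, masked_mode = "neg",
                          metabolite_of = NULL,
                          normalization = c("tic", "pqn", "none"), ...) {
  design <- match.arg(design)
  normalization <- match.arg(normalization)
  agg <- if (inherits(datasets, "aggregate_matrix")) {
    datasets
  } else {
    if (inherits(datasets, "raw_dataset")) datasets <- list(datasets)
    aggregate_ranked(lapply(datasets, function(d) {
      rank_transform(normalize_dataset(d, method = normalization))
    }))
  }
  scores <- purrr::map_dfr(seq_len(trials), function(t) {
    tseed <- derive_seed(seed, "trial", t)
    plan <- switch(design,
      within = make_mask_within(agg, frac_samples = frac_samples,
                                frac_features = frac_features, seed = tseed),
      across = make_mask_across(agg, target = target,
                                frac_features = frac_features, seed = tseed),
      mode = make_mask_mode(agg, modes = modes, masked_mode = masked_mode,
                            frac_samples = frac_samples, seed = tseed,
                            metabolite_of = metabolite_of))
    masked <- apply_mask(agg, plan)
    imp <- mirth_impute(masked, k = k, seed = tseed, ...)
    sc <- score_trial(agg, imp, plan)
    sc$q <- NA_real_
    sc$q[sc$scored] <- bh_adjust(sc$p[sc$scored])
    sc$trial <- t
    sc
  })
  structure(list(scores = scores, design = design, k = k, trials = trials,
                 seed = as.integer(seed),
                 dims = dim(agg$values), batch = agg$batch),
            class = "mirth_benchmark")
}

#' @export
print.mirth_benchmark <- function(x, ...) {
  cat(sprintf("<mirth_benchmark '%s'> %d trials, k = %s; %d feature scores\n",
              x$design, x$trials, x$k, nrow(x$scores)))
  invisible(x)
}

#' Classify features as well-predicted across trials
#'
#' A feature is *well-predicted* when it shows a significant positive
#' correlation with truth (`rho > 0` and BH `q < 0.05`) in strictly more
#' than `min_frac` (default 90%) of the trials in which it was scored.
#'
#' @param scores Tibble of trial scores with columns `feature`, `rho`, `q`
#'   (and optionally `scored`), e.g. `run_benchmark(...)$scores`; a
#'   `mirth_benchmark` is accepted.
#' @param min_frac Strict lower bound on the significant-trial fraction.
#' @param alpha Significance level on q.
#' @return Tibble: `feature`, `n_trials`, `frac_significant`,
#'   `well_predicted`, `rho_summary` (Fisher-z median of per-trial rho).
#' @export
classify_well_predicted <- function(scores, min_frac = 0.9, alpha = 0.05) {
  if (inherits(scores, "mirth_benchmark")) scores <- scores$scores
  if ("scored" %in% names(scores)) scores <- scores[scores$scored %in% TRUE, ]
  if (nrow(scores) == 0) abort("no scored trials")
  scores |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      frac_significant = mean(.data$rho > 0 & .data$q < alpha),
      rho_summary = summarize_rho(.data$rho),
      .groups = "drop"
    ) |>
    dplyr::mutate(well_predicted = .data$frac_significant > min_frac)
}

#' Reproducibly well-predicted features across batches
#'
#' A feature is *reproducibly well-predicted* when it is measured in at
#' least `min_batches` batches and well-predicted in at least `min_frac`
#' (three-quarters) of the batches in which it is measured.
#'
#' @param flags Tibble with columns `feature`, `batch`, `well_predicted`
#'   (one row per feature per batch, e.g. from per-target
#'   [classify_well_predicted()] runs bound together).
#' @param measured_in Tibble with columns `feature`, `batch` listing where
#'   each feature is measured; defaults to the batches present in `flags`.
#' @param min_batches,min_frac Thresholds (defaults 4 and 3/4).
#' @return Tibble: `feature`, `n_measured`, `n_well`,
#'   `reproducibly_well_predicted`.
#' @export
classify_reproducible <- function(flags, measured_in = NULL, min_batches = 4L,
                                  min_frac = 0.75) {
  measured_in <- measured_in %||% flags[, c("feature", "batch")]
  meas <- measured_in |>
    dplyr::distinct(.data$feature, .data$batch) |>
    dplyr::count(.data$feature, name = "n_measured")
  well <- flags |>
    dplyr::filter(.data$well_predicted) |>
    dplyr::distinct(.data$feature, .data$batch) |>
    dplyr::count(.data$feature, name = "n_well")
  meas |>
    dplyr::left_join(well, by = "feature") |>
    dplyr::mutate(
      n_well = dplyr::coalesce(.data$n_well, 0L),
      reproducibly_well_predicted =
        .data$n_measured >= min_batches &
        .data$n_well >= min_frac * .data$n_measured
    )
}

#' Pathway enrichment of embedding dimensions
#'
#' For each embedding dimension, features with weight above `cutoff` in that
#' row of `H` are called appreciably weighted; each pathway is then tested
#' for enrichment among them by a two-sided Fisher's exact test on the 2x2
#' table (appreciably weighted x pathway membership), over the universe of
#' annotated features present in `H`. P-values are BH-adjusted across all
#' (dimension, pathway) tests.
#'
#' @param model A `mirth_nmf` object (or the `H` matrix itself).
#' @param annotations Tibble/data frame with columns `feature`, `pathway`
#'   (first two columns used).
#' @param cutoff Weight threshold (default 0.2).
#' @return Tibble: `dimension`, `pathway`, `n_weighted`, `n_pathway`,
#'   `overlap`, `odds_ratio`, `p`, `q`; zero rows when no feature passes the
#'   cutoff.
#' @export
enrichment_by_dimension <- function(model, annotations, cutoff = 0.2) {
  H <- if (inherits(model, "mirth_nmf")) model$H else model
  ann <- tibble::tibble(feature = as.character(annotations[[1]]),
                        pathway = as.character(annotations[[2]]))
  ann <- ann[ann$feature %in% colnames(H), , drop = FALSE]
  universe <- unique(ann$feature)
  if (length(universe) == 0) abort("no annotated feature appears in the model")
  pathways <- split(ann$feature, ann$pathway)
  out <- purrr::map_dfr(seq_len(nrow(H)), function(d) {
    hot <- universe[H[d, universe] > cutoff]
    if (length(hot) == 0) return(tibble::tibble())
    purrr::map_dfr(names(pathways), function(pw) {
      members <- unique(pathways[[pw]])
      a <- sum(hot %in% members)
      b <- length(hot) - a
      c_ <- sum(!(members %in% hot))
      d_ <- length(universe) - a - b - c_
      ft <- fisher.test(matrix(c(a, b, c_, d_), 2, 2, byrow = TRUE),
                        alternative = "two.sided")
      tibble::tibble(dimension = d, pathway = pw, n_weighted = length(hot),
                     n_pathway = length(members), overlap = a,
                     odds_ratio = unname(ft$estimate), p = ft$p.value)
    })
  })
  if (nrow(out) > 0) out$q <- bh_adjust(out$p)
  out
}
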