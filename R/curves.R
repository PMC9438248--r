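#' Imputation performance against masking fraction (controlled design)
#'
#' Measures how across-batch imputation degrades as a growing share of a
#' target batch's shared features is simulated unmeasured. To isolate the
#' effect of losing training data from the composition of the scored set,
#' the masks are *nested* (the 30% set contains the 10% set, and so on) and
#' every condition is scored on the same base subset — the features masked
#' at the smallest fraction — so differences reflect only the information
#' removed from training.
#'
#' @param fractions Increasing masking fractions (default 0.1, 0.3, 0.5).
#' @param config A [sim_config()] describing the synthetic cohorts.
#' @param target Target batch id (default `"batch2"`).
#' @param k Embedding dimensions for the fits (default the config's true
#'   rank).
#' @param n_seeds Replicate simulations per condition.
#' @param seed Root seed.
#' @param ... Passed to [fit_nmf_masked()] via [mirth_impute()].
#' @return Tibble: `fraction`, `replicate`, `rho` (summarized over the base
#'   features).
#' @export
masking_fraction_curve <- function(fractions = c(0.1, 0.3, 0.5),
                                   config = sim_config(), target = "batch2",
                                   k = config$k_star, n_seeds = 20L,
                                   seed = 1L, ...) {
  if (is.unsorted(fractions, strictly = TRUE)) {
    abort("`fractions` must be strictly increasing")
  }
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    sseed <- derive_seed(seed, "mask-curve", s)
    cfg <- config
    cfg$seed <- sseed
    sim <- simulate_batches(cfg)
    agg <- suppressMessages(aggregate_ranked(
      lapply(sim$datasets, function(d) rank_transform(normalize_dataset(d)))))
    shared <- eligible_features(agg)[[target]]
    ord <- with_seed(derive_seed(sseed, "order"), sample(shared))
    base <- ord[seq_len(max(1L, round(fractions[1] * length(shared))))]
    rows <- agg$batch == target
    purrr::map_dfr(fractions, function(fr) {
      sel <- ord[seq_len(max(1L, round(fr * length(shared))))]
      mask <- matrix(FALSE, nrow(agg$values), ncol(agg$values),
                     dimnames = dimnames(agg$values))
      mask[rows, sel] <- TRUE
      plan <- new_mask_plan("across", mask & agg$observed,
                            rownames(agg$values)[rows], base, sseed,
                            target = target)
      imp <- suppressMessages(mirth_impute(apply_mask(agg, plan), k = k,
                                           seed = sseed, ...))
      sc <- score_trial(agg, imp, plan)
      tibble::tibble(fraction = fr, replicate = s,
                     rho = summarize_rho(sc$rho[sc$scored]))
    })
  })
}

#' Imputation performance against training sample size
#'
#' Compares across-batch imputation at several per-batch sample counts with
#' everything else held fixed: each replicate simulates one cohort at the
#' largest size and the smaller conditions use the first `n` samples of each
#' batch (same latent structure, same measured feature subsets, same batch
#' effects, same masked features), so within a replicate the conditions
#' differ only in the amount of training data. Each sub-cohort is
#' preprocessed (normalized, rank-transformed) on its own samples.
#'
#' @param sizes Samples per batch to compare (default 10, 30, 100).
#' @param config Base [sim_config()]; its `samples_per_batch` is set to
#'   `max(sizes)` for the simulation.
#' @param target,k,n_seeds,seed,... As in [masking_fraction_curve()].
#' @param frac_features Masking fraction for the across design.
#' @return Tibble: `samples_per_batch`, `replicate`, `rho` (summarized over
#'   the masked features).
#' @export
sample_size_curve <- function(sizes = c(10L, 30L, 100L), config = sim_config(),
                              target = "batch2", frac_features = 0.1,
                              k = config$k_star, n_seeds = 30L, seed = 1L, ...) {
  sizes <- sort(as.integer(sizes))
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    sseed <- derive_seed(seed, "size-curve", s)
    cfg <- config
    cfg$samples_per_batch <- rep(max(sizes), cfg$n_batches)
    cfg$seed <- sseed
    sim <- simulate_batches(cfg)
    pool <- eligible_features(sim$datasets)[[target]]
    n_f <- max(1L, round(frac_features * length(pool)))
    masked_feats <- with_seed(derive_seed(sseed, "feats"), sort(sample(pool, n_f)))
    purrr::map_dfr(sizes, function(n) {
      sub <- lapply(sim$datasets, function(d) {
        raw_dataset(d$values[seq_len(n), , drop = FALSE], batch_id = d$batch_id,
                    censored = d$censored[seq_len(n), , drop = FALSE])
      })
      agg <- suppressMessages(aggregate_ranked(
        lapply(sub, function(d) rank_transform(normalize_dataset(d)))))
      rows <- agg$batch == target
      mask <- matrix(FALSE, nrow(agg$values), ncol(agg$values),
                     dimnames = dimnames(agg$values))
      mask[rows, masked_feats] <- TRUE
      plan <- new_mask_plan("across", mask & agg$observed,
                            rownames(agg$values)[rows], masked_feats, sseed,
                            target = target)
      imp <- suppressMessages(mirth_impute(apply_mask(agg, plan), k = k,
                                           seed = sseed, ...))
      sc <- score_trial(agg, imp, plan)
      tibble::tibble(samples_per_batch = n, replicate = s,
                     rho = summarize_rho(sc$rho[sc$scored]))
    })
  })
}
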