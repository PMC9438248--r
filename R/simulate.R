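#' Configuration for the synthetic multi-batch generator
#'
#' The generator emulates the structure the imputation model assumes: a
#' shared nonnegative low-rank latent abundance matrix, batches that each
#' measure only a subset of the features, per-batch strictly-monotone
#' shape-and-scale distortions `Y = f(alpha * Y* + beta)`, multiplicative
#' log-normal measurement noise, and left-censoring of each feature's low
#' tail at a detection threshold.
#'
#' Latent factors are drawn from right-skewed gamma distributions (sample
#' factors gamma(2, 1); feature factors gamma(0.7, 1), so feature loadings
#' are sparse-ish with most weights small).
#'
#' @param n_batches Number of batches (default 3).
#' @param samples_per_batch Samples per batch (scalar or vector; default 20).
#' @param n_features Total features across batches (default 50).
#' @param k_star True latent rank (default 3).
#' @param noise_sd SD of multiplicative log-normal noise (default 0.1,
#'   mild).
#' @param measured_fraction Fraction of features measured per batch
#'   (scalar or per-batch; default 0.8). Every feature is guaranteed to be
#'   measured in at least one batch.
#' @param censor_quantile Per-feature fraction of the low tail censored in
#'   each batch, in `[0, 0.9]` (default 0.05); exactly
#'   `floor(censor_quantile * N)` entries per measured feature.
#' @param batch_effects Optional list (length `n_batches`) of lists with
#'   `alpha` (> 0), `beta` (>= 0), `f` in `{"identity", "log1p", "power"}`
#'   and optionally `gamma` (power exponent); drawn from the seed when
#'   `NULL` (alpha ~ U(0.5, 2), beta ~ U(0, 0.5), f cycling the families).
#' @param seed Seed; the simulation is fully deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_batches = 3L, samples_per_batch = 20L, n_features = 50L,
                       k_star = 3L, noise_sd = 0.1, measured_fraction = 0.8,
                       censor_quantile = 0.05, batch_effects = NULL, seed = 1L) {
  cfg <- list(n_batches = as.integer(n_batches),
              samples_per_batch = rep(as.integer(samples_per_batch),
                                      length.out = n_batches),
              n_features = as.integer(n_features),
              k_star = as.integer(k_star),
              noise_sd = noise_sd,
              measured_fraction = rep(measured_fraction, length.out = n_batches),
              censor_quantile = rep(censor_quantile, length.out = n_batches),
              batch_effects = batch_effects,
              seed = as.integer(seed))
  if (cfg$k_star > min(sum(cfg$samples_per_batch), cfg$n_features)) {
    abort("`k_star` must not exceed min(total samples, n_features)")
  }
  if (any(cfg$censor_quantile < 0 | cfg$censor_quantile > 0.9)) {
    abort("`censor_quantile` must lie in [0, 0.9]")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be nonnegative")
  if (any(cfg$measured_fraction <= 0 | cfg$measured_fraction > 1)) {
    abort("`measured_fraction` must lie in (0, 1]")
  }
  structure(cfg, class = "sim_config")
}

apply_monotone <- function(x, eff) {
  y <- eff$alpha * x + eff$beta
  switch(eff$f,
         identity = y,
         log1p = log1p(y),
         power = y^(eff$gamma %||% 0.7),
         abort(sprintf("unknown monotone family '%s'", eff$f)))
}

#' Simulate multi-batch metabolomics data with known ground truth
#'
#' Draws `W*` (total samples x k*) and `H*` (k* x features) from gamma
#' distributions, forms the true abundance matrix `Y* = W* H*`, applies
#' entrywise multiplicative log-normal noise, and splits samples into
#' batches. Each batch measures a random feature subset, distorts its block
#' by a strictly monotone shape-and-scale effect, and censors each measured
#' feature's lowest `censor_quantile` fraction (those entries become `NA`
#' with the censored flag set).
#'
#' @param config A [sim_config()].
#' @return A list with `datasets` (list of [raw_dataset()]), and `truth`:
#'   `W_star`, `H_star`, `Y_star`, per-batch row indices, measured feature
#'   sets, batch-effect parameters, and per-batch true rank matrices of
#'   `Y*` (censoring-free, computed per batch).
#' @export
simulate_batches <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  m <- sum(cfg$samples_per_batch)
  with_seed(derive_seed(cfg$seed, "simulate"), {
    # H first: configs differing only in sample count then share the same
    # latent feature structure under the same seed (pairs conditions)
    H <- matrix(rgamma(cfg$k_star * cfg$n_features, shape = 0.7, scale = 1),
                cfg$k_star, cfg$n_features)
    W <- matrix(rgamma(m * cfg$k_star, shape = 2, scale = 1), m, cfg$k_star)
    Y <- W %*% H
    noisy <- Y * matrix(rlnorm(length(Y), 0, cfg$noise_sd), nrow(Y))

    feats <- paste0("met", seq_len(cfg$n_features))
    colnames(Y) <- colnames(noisy) <- feats
    rownames(Y) <- rownames(noisy) <- paste0("s", seq_len(m))

    n_meas <- pmax(1L, round(cfg$measured_fraction * cfg$n_features))
    measured <- lapply(seq_len(cfg$n_batches),
                       function(b) sort(sample(feats, n_meas[b])))
    orphan <- setdiff(feats, unique(unlist(measured)))
    for (f in orphan) {  # guarantee every feature is measured somewhere
      b <- sample(cfg$n_batches, 1)
      measured[[b]] <- sort(union(measured[[b]], f))
    }

    effects <- cfg$batch_effects %||% lapply(seq_len(cfg$n_batches), function(b) {
      list(alpha = runif(1, 0.5, 2), beta = runif(1, 0, 0.5),
           f = c("identity", "log1p", "power")[(b - 1L) %% 3L + 1L],
           gamma = runif(1, 0.5, 1.5))
    })

    ends <- cumsum(cfg$samples_per_batch)
    starts <- c(1L, head(ends, -1) + 1L)
    datasets <- vector("list", cfg$n_batches)
    true_ranks <- vector("list", cfg$n_batches)
    rows_of <- vector("list", cfg$n_batches)
    for (b in seq_len(cfg$n_batches)) {
      rows <- starts[b]:ends[b]
      rows_of[[b]] <- rows
      block <- apply_monotone(noisy[rows, measured[[b]], drop = FALSE], effects[[b]])
      n <- nrow(block)
      cens <- matrix(FALSE, n, ncol(block), dimnames = dimnames(block))
      n_cens <- floor(cfg$censor_quantile[b] * n)
      if (n_cens > 0) {
        for (j in seq_len(ncol(block))) {
          cens[order(block[, j])[seq_len(n_cens)], j] <- TRUE
        }
      }
      vals <- block
      vals[cens] <- NA_real_
      datasets[[b]] <- raw_dataset(vals, batch_id = paste0("batch", b),
                                   censored = cens)
      true_ranks[[b]] <- apply(Y[rows, measured[[b]], drop = FALSE], 2,
                               function(x) rank(x, ties.method = "min") / (n + 1))
      rownames(true_ranks[[b]]) <- rownames(block)
    }
    list(datasets = datasets,
         truth = list(W_star = W, H_star = H, Y_star = Y,
                      rows_of_batch = rows_of, measured = measured,
                      effects = effects, true_ranks = true_ranks),
         config = cfg)
  })
}

#' Packaged small simulation scenarios
#'
#' A registry of seeded scenarios used across the documentation and test
#' suite:
#' * `tiny-within`: one batch, 20 samples, 15 features, true rank 2.
#' * `tiny-across`: three batches of 10 samples, 20 features, true rank 2.
#' * `tiny-mode`: one batch, 16 samples, 12 features carrying pos/neg
#'   ionization-mode labels, 4 of them single-mode (returned as `modes` and
#'   `metabolite_of`).
#' * `rank3-recovery`: three batches of 20 samples (60 total), 50 features,
#'   true rank 3, mild noise — the dimension-selection test bed.
#'
#' @param name Scenario name.
#' @param seed Seed (default 42).
#' @return The [simulate_batches()] result, plus scenario extras.
#' @export
make_fixture <- function(name, seed = 42L) {
  registry <- list(
    `tiny-within` = function(seed) {
      simulate_batches(sim_config(n_batches = 1, samples_per_batch = 20,
                                  n_features = 15, k_star = 2, seed = seed))
    },
    `tiny-across` = function(seed) {
      simulate_batches(sim_config(n_batches = 3, samples_per_batch = 10,
                                  n_features = 20, k_star = 2, seed = seed))
    },
    `tiny-mode` = function(seed) {
      out <- simulate_batches(sim_config(n_batches = 1, samples_per_batch = 16,
                                         n_features = 12, k_star = 2,
                                         measured_fraction = 1, seed = seed))
      feats <- colnames(out$datasets[[1]]$values)
      # features 1-8 are 4 metabolites each quantified in both modes;
      # features 9-12 are single-mode (2 pos-only, 2 neg-only)
      modes <- setNames(c(rep(c("pos", "neg"), 4), "pos", "pos", "neg", "neg"),
                        feats)
      metab <- setNames(c(rep(paste0("m", 1:4), each = 2), paste0("solo", 1:4)),
                        feats)
      out$modes <- modes
      out$metabolite_of <- metab
      out
    },
    `rank3-recovery` = function(seed) {
      simulate_batches(sim_config(n_batches = 3, samples_per_batch = 20,
                                  n_features = 50, k_star = 3, seed = seed))
    }
  )
  if (!name %in% names(registry)) {
    abort(sprintf("unknown fixture '%s'; available: %s", name,
                  paste(names(registry), collapse = ", ")))
  }
  registry[[name]](seed)
}
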