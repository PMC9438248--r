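#' Masking designs for benchmarking imputation
#'
#' Each design builds a `mask_plan` describing which observed cells of the
#' rank-transformed aggregate are hidden before imputation, so imputed ranks
#' can be scored against known truth:
#'
#' * **within** — in one batch, a random fraction of features is masked in a
#'   random fraction of the samples, splitting the batch into two
#'   pseudo-datasets (one measuring fewer features).
#' * **across** — in a designated target batch, a random fraction of the
#'   features shared with other batches is masked in *all* target samples,
#'   simulating entirely-unmeasured metabolites.
#' * **mode** — all features of one ionization mode are masked in a random
#'   half of the samples; evaluation is restricted to features measured in
#'   only one mode.
#'
#' @param agg An `aggregate_matrix` (see [aggregate_ranked()]).
#' @param frac_samples,frac_features Fractions in (0,1); counts are rounded
#'   and must be >= 1.
#' @param seed Seed making the plan reproducible.
#' @return A `mask_plan`: `design`, logical `mask` (same shape as the
#'   aggregate), `held_samples`, `held_features`, `seed`, and design extras.
#' @name mask_plans
NULL

new_mask_plan <- function(design, mask, held_samples, held_features, seed, ...) {
  structure(list(design = design, mask = mask, held_samples = held_samples,
                 held_features = held_features, seed = as.integer(seed), ...),
            class = "mask_plan")
}

#' @rdname mask_plans
#' @param batch Batch to split (defaults to the aggregate's only batch).
#' @export
make_mask_within <- function(agg, frac_samples = 0.5, frac_features = 0.1,
                             seed = 1L, batch = NULL) {
  stopifnot(inherits(agg, "aggregate_matrix"))
  if (frac_samples <= 0 || frac_samples >= 1 || frac_features <= 0 || frac_features >= 1) {
    abort("fractions must lie strictly in (0, 1)")
  }
  batch <- batch %||% unique(agg$batch)[1]
  rows <- which(agg$batch == batch)
  feats <- colnames(agg$values)[colSums(agg$observed[rows, , drop = FALSE]) > 0]
  n_s <- round(frac_samples * length(rows))
  n_f <- round(frac_features * length(feats))
  if (n_s < 1 || n_f < 1) abort("fractions select zero samples or features")
  if (n_f >= length(feats)) abort("cannot hold out every feature of the batch")
  sel <- with_seed(derive_seed(seed, "within"), {
    list(s = sort(sample(rows, n_s)), f = sort(sample(feats, n_f)))
  })
  mask <- matrix(FALSE, nrow(agg$values), ncol(agg$values), dimnames = dimnames(agg$values))
  mask[sel$s, sel$f] <- TRUE
  mask <- mask & agg$observed
  new_mask_plan("within", mask, rownames(agg$values)[sel$s], sel$f, seed, batch = batch)
}

#' @rdname mask_plans
#' @param target Target batch id whose features are masked entirely.
#' @param on_unimputable `"error"` (default) or `"redraw"`: policy when a
#'   drawn feature is measured nowhere else (candidates are restricted to
#'   shared features, so this only matters with a user-supplied pool).
#' @param candidates Optional explicit candidate feature pool.
#' @export
make_mask_across <- function(agg, target, frac_features = 0.1, seed = 1L,
                             candidates = NULL, on_unimputable = c("error", "redraw")) {
  stopifnot(inherits(agg, "aggregate_matrix"))
  on_unimputable <- match.arg(on_unimputable)
  if (!target %in% agg$batch) abort(sprintf("unknown target batch '%s'", target))
  if (frac_features <= 0 || frac_features >= 1) abort("`frac_features` must lie in (0, 1)")
  rows <- which(agg$batch == target)
  shared <- eligible_features(agg)[[target]]
  pool <- candidates %||% shared
  bad <- setdiff(pool, shared)
  if (length(bad) > 0) {
    if (on_unimputable == "error") {
      abort(sprintf("feature(s) measured nowhere outside the target: %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
    pool <- setdiff(pool, bad)
  }
  n_f <- round(frac_features * length(pool))
  if (n_f < 1) abort("`frac_features` selects zero features")
  sel <- with_seed(derive_seed(seed, "across"), sort(sample(pool, n_f)))
  mask <- matrix(FALSE, nrow(agg$values), ncol(agg$values), dimnames = dimnames(agg$values))
  mask[rows, sel] <- TRUE
  mask <- mask & agg$observed
  new_mask_plan("across", mask, rownames(agg$values)[rows], sel, seed, target = target)
}

#' @rdname mask_plans
#' @param modes Named character vector: ionization mode (`"pos"`/`"neg"`)
#'   per feature.
#' @param masked_mode Which mode's features to mask (default `"neg"`).
#' @param metabolite_of Optional named vector mapping feature id to
#'   metabolite; a metabolite quantified in both modes appears as two
#'   features. Defaults to the feature ids themselves (every metabolite
#'   single-mode). Evaluation is restricted to single-mode metabolites.
#' @export
make_mask_mode <- function(agg, modes, masked_mode = "neg", frac_samples = 0.5,
                           seed = 1L, metabolite_of = NULL) {
  stopifnot(inherits(agg, "aggregate_matrix"))
  feats <- colnames(agg$values)
  missing_lab <- setdiff(feats, names(modes))
  if (length(missing_lab) > 0) {
    abort(sprintf("feature(s) without a mode label: %s",
                  paste(head(missing_lab, 5), collapse = ", ")))
  }
  metabolite_of <- metabolite_of %||% setNames(feats, feats)
  mode_feats <- feats[unname(modes[feats]) == masked_mode]
  if (length(mode_feats) == length(feats)) {
    abort("every feature is in the masked mode; masking would empty the samples")
  }
  if (length(mode_feats) == 0) abort(sprintf("no features in mode '%s'", masked_mode))
  rows <- seq_len(nrow(agg$values))
  n_s <- round(frac_samples * length(rows))
  if (n_s < 1) abort("`frac_samples` selects zero samples")
  sel_s <- with_seed(derive_seed(seed, "mode"), sort(sample(rows, n_s)))
  mask <- matrix(FALSE, nrow(agg$values), ncol(agg$values), dimnames = dimnames(agg$values))
  mask[sel_s, mode_feats] <- TRUE
  mask <- mask & agg$observed
  # scoring is restricted to metabolites measured in only one mode
  n_modes <- tapply(unname(modes[feats]), unname(metabolite_of[feats]),
                    function(m) length(unique(m)))
  single_metab <- names(n_modes)[n_modes == 1]
  single <- feats[unname(metabolite_of[feats]) %in% single_metab]
  new_mask_plan("mode", mask, rownames(agg$values)[sel_s],
                intersect(mode_feats, single), seed,
                masked_mode = masked_mode, modes = modes)
}

#' Apply a mask plan to an aggregate rank matrix
#'
#' @param agg An `aggregate_matrix`.
#' @param plan A `mask_plan`.
#' @return The aggregate with masked cells set unobserved (`NA`).
#' @export
apply_mask <- function(agg, plan) {
  stopifnot(inherits(agg, "aggregate_matrix"), inherits(plan, "mask_plan"))
  out <- agg
  out$observed[plan$mask] <- FALSE
  out$values[plan$mask] <- NA_real_
  out
}

#' @export
print.mask_plan <- function(x, ...) {
  cat(sprintf("<mask_plan '%s'> %d cells masked (%d features x %d samples held out)\n",
              x$design, sum(x$mask), length(x$held_features), length(x$held_samples)))
  invisible(x)
}
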