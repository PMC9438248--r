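#' @importFrom rlang abort warn .data
#' @importFrom stats median optim p.adjust cor.test fisher.test quantile rgamma
#'   rlnorm runif setNames
#' @importFrom utils head
NULL

# Deterministic substream seed: every stochastic operation draws its seed from
# the user-facing seed plus a short tag, so e.g. changing the number of trials
# never perturbs earlier trials' draws. Kept below 2^31 - 1.
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) + 10007 * h + 999983 * index) %% (.Machine$integer.max - 1L)) + 1L
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
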