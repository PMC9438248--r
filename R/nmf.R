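#' Nonnegative matrix factorization with unobserved entries omitted
#'
#' Factorizes the aggregate rank matrix `X` (m samples x n features, values
#' in (0,1), `NA` where a feature is unmeasured in a sample's batch) as
#' `X ~ W %*% H` with `W >= 0` (m x k sample embeddings) and `H >= 0`
#' (k x n feature embeddings), minimizing the sum of squared residuals over
#' *observed* entries only:
#' \deqn{\min_{W,H \ge 0} \sum_{(i,j)\,observed} (x_{ij} - w_i^\top h_j)^2}
#' Because the loss is an entrywise sum, unobserved cells simply drop out of
#' the objective, and the dense product `W %*% H` supplies predictions for
#' them.
#'
#' Two backends share this contract: `"lbfgsb"` (default) runs
#' bound-constrained quasi-Newton (`stats::optim`, lower bound 0) on the
#' concatenated `(W, H)` vector with analytic gradients; `"mu"` runs masked
#' multiplicative updates (Lee-Seydoux style, with unobserved cells zeroed in
#' both numerator and denominator), which is cheaper per iteration on larger
#' problems. Initial `W`, `H` are i.i.d. uniform, scaled so the initial
#' product matches the mean observed value; with `n_restarts > 1` the lowest
#' final loss wins. The returned loss never exceeds the loss at
#' initialization.
#'
#' @param X An `aggregate_matrix` or a plain numeric matrix with `NA` for
#'   unobserved entries.
#' @param k Number of embedding dimensions, `1 <= k <= min(m, n)`.
#' @param seed Integer seed; the fit is deterministic given `(X, k, seed)`.
#' @param max_iter Iteration cap (default 2000).
#' @param tol Relative-change convergence tolerance on the masked loss.
#' @param backend `"lbfgsb"` or `"mu"`.
#' @param n_restarts Independent seeded restarts; best kept.
#' @return A `mirth_nmf` object: `W`, `H`, `k`, `final_loss`, `converged`,
#'   `n_iter`, `seed`, `backend`, plus the row/column labels of `X`.
#' @export
fit_nmf_masked <- function(X, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                           backend = c("lbfgsb", "mu"), n_restarts = 1L) {
  backend <- match.arg(backend)
  agg <- as_aggregate(X)
  x <- agg$values
  obs <- agg$observed & !is.na(x)
  m <- nrow(x); n <- ncol(x)
  assert_scalar_number(k, "k", lower = 1, upper = min(m, n))
  k <- as.integer(k)
  zr <- which(rowSums(obs) == 0)
  if (length(zr) > 0) {
    abort(sprintf("sample(s) with no observed entry: %s",
                  paste(head(rownames(x)[zr], 5), collapse = ", ")))
  }
  zc <- which(colSums(obs) == 0)
  if (length(zc) > 0) {
    abort(sprintf("feature(s) with no observed entry: %s",
                  paste(head(colnames(x)[zc], 5), collapse = ", ")))
  }
  x0 <- x
  x0[!obs] <- 0
  mean_obs <- sum(x0) / sum(obs)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    rseed <- derive_seed(seed, "nmf-init", r - 1L)
    init <- with_seed(rseed, {
      s <- sqrt(mean_obs / max(k, 1))
      list(W = matrix(2 * s * runif(m * k), m, k),
           H = matrix(2 * s * runif(k * n), k, n))
    })
    fit <- switch(backend,
                  lbfgsb = nmf_lbfgsb(x0, obs, init, max_iter, tol),
                  mu = nmf_mu(x0, obs, init, max_iter, tol))
    if (is.null(best) || fit$final_loss < best$final_loss) best <- fit
  }

  dimnames(best$W) <- list(rownames(x), paste0("dim", seq_len(k)))
  dimnames(best$H) <- list(paste0("dim", seq_len(k)), colnames(x))
  structure(
    list(W = best$W, H = best$H, k = k, final_loss = best$final_loss,
         converged = best$converged, n_iter = best$n_iter,
         init_loss = best$init_loss, seed = as.integer(seed),
         backend = backend, batch = agg$batch, observed = obs),
    class = "mirth_nmf"
  )
}

masked_loss <- function(W, H, x0, obs) {
  r <- W %*% H - x0
  r[!obs] <- 0
  sum(r * r)
}

nmf_lbfgsb <- function(x0, obs, init, max_iter, tol) {
  m <- nrow(x0); n <- ncol(x0); k <- ncol(init$W)
  nw <- m * k
  unpack <- function(par) list(W = matrix(par[seq_len(nw)], m, k),
                               H = matrix(par[-seq_len(nw)], k, n))
  fn <- function(par) {
    p <- unpack(par)
    masked_loss(p$W, p$H, x0, obs)
  }
  gr <- function(par) {
    p <- unpack(par)
    r <- p$W %*% p$H - x0
    r[!obs] <- 0
    c(2 * (r %*% t(p$H)), 2 * (t(p$W) %*% r))
  }
  par0 <- c(init$W, init$H)
  f0 <- fn(par0)
  # factr scales the machine epsilon into a relative-change stop rule
  res <- optim(par0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = max_iter,
                              factr = max(tol / .Machine$double.eps, 10)))
  if (res$value > f0) {  # guard: never return worse than the start
    res$par <- par0
    res$value <- f0
  }
  p <- unpack(res$par)
  list(W = p$W, H = p$H, final_loss = res$value, init_loss = f0,
       converged = res$convergence == 0, n_iter = res$counts[["function"]])
}

nmf_mu <- function(x0, obs, init, max_iter, tol) {
  W <- init$W; H <- init$H
  eps <- 1e-12
  obs_num <- x0  # x0 already has unobserved cells zeroed
  f0 <- masked_loss(W, H, x0, obs)
  prev <- f0
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    WH[!obs] <- 0
    W <- W * (obs_num %*% t(H)) / (WH %*% t(H) + eps)
    WH <- W %*% H
    WH[!obs] <- 0
    H <- H * (t(W) %*% obs_num) / (t(W) %*% WH + eps)
    if (it %% 10 == 0 || it == max_iter) {
      cur <- masked_loss(W, H, x0, obs)
      if (prev - cur < tol * max(prev, eps)) {
        converged <- TRUE
        prev <- cur
        break
      }
      prev <- cur
    }
  }
  final <- masked_loss(W, H, x0, obs)
  if (final > f0) {
    W <- init$W; H <- init$H; final <- f0
  }
  list(W = W, H = H, final_loss = final, init_loss = f0,
       converged = converged, n_iter = it)
}

#' Reconstruct the dense matrix from a factor model
#'
#' @param model A `mirth_nmf` object.
#' @return The m x n nonnegative product `W %*% H`, with no missing entries.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "mirth_nmf"))
  model$W %*% model$H
}

#' @export
print.mirth_nmf <- function(x, ...) {
  cat(sprintf("<mirth_nmf> k = %d, %d x %d, masked loss %.4g (%s, %s)\n",
              x$k, nrow(x$W), ncol(x$H), x$final_loss, x$backend,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
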