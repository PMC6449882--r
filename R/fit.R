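#' Fitting configuration
#'
#' Optimizer and penalty settings for [fit_scnbmf()].
#'
#' @param n_components number of latent factors K (default 20).
#' @param learning_rate Adam step size (default 0.001).
#' @param max_iter maximum full-batch iterations (default 18000).
#' @param lambda LASSO penalty on the loadings W (default 1).
#' @param seed RNG seed for the factor initialization.
#' @param rel_tol early-stopping tolerance: the fit stops when the relative
#'   change between consecutive 100-iteration moving averages of the
#'   objective falls below this (default 1e-6).
#' @param phi_min,phi_max clamp bounds applied to supplied dispersions.
#' @param log_mean_bound clamp on |log(mu/N)| during optimization (default 30;
#'   counts never justify rates beyond e^30 times depth).
#' @param optimizer one of `"adam"` (default, the only one covered by the
#'   package's benchmarks), `"sgd"`, `"adagrad"`, `"momentum"`.
#' @param penalty_method `"subgradient"` (default): the l1 term contributes
#'   `lambda * sign(W)` with sign(0) = 0 inside the optimizer, matching what
#'   plain automatic differentiation of the objective does; `"proximal"`:
#'   soft-threshold W after each smooth step instead.
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_components = 20L, learning_rate = 0.001,
                       max_iter = 18000L, lambda = 1.0, seed = 1L,
                       rel_tol = 1e-6, phi_min = 1e-3, phi_max = 1e8,
                       log_mean_bound = 30,
                       optimizer = c("adam", "sgd", "adagrad", "momentum"),
                       penalty_method = c("subgradient", "proximal")) {
  stop_if_not_scalar_pos(learning_rate, "learning_rate")
  stop_if_not_scalar_pos(n_components, "n_components")
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (rel_tol < 0) stop("`rel_tol` must be >= 0", call. = FALSE)
  structure(list(
    n_components = as.integer(n_components),
    learning_rate = learning_rate,
    max_iter = as.integer(max_iter),
    lambda = lambda,
    seed = as.integer(seed),
    rel_tol = rel_tol,
    phi_min = phi_min, phi_max = phi_max,
    log_mean_bound = log_mean_bound,
    optimizer = match.arg(optimizer),
    penalty_method = match.arg(penalty_method)
  ), class = "fit_config")
}

#' Random factor initialization
#'
#' Fills W (p x K) and H (K x n) with zero-mean Gaussian entries of standard
#' deviation `0.01/sqrt(K)`, so the initial log-rates `W %*% H` are near zero
#' (means near the depth offsets) regardless of K. Reproducible for a fixed
#' seed.
#'
#' @param p,n,K dimensions; `K <= min(p, n)`.
#' @param seed RNG seed.
#' @return a [factor_model()].
#' @export
init_factors <- function(p, n, K, seed = 1L) {
  if (K < 1L || K > min(p, n))
    stop("`K` must satisfy 1 <= K <= min(p, n)", call. = FALSE)
  sd0 <- 0.01 / sqrt(K)
  with_seed(seed, {
    W <- matrix(stats::rnorm(p * K, 0, sd0), p, K)
    H <- matrix(stats::rnorm(K * n, 0, sd0), K, n)
    factor_model(W, H)
  })
}

#' Gradient of the penalized objective
#'
#' Closed-form gradient of the minimization objective with respect to W and
#' H. The smooth part chains the per-entry derivative
#' \deqn{\partial(-\ell)/\partial(WH)_{ij} = (y_{ij}+\phi_i)\,
#'   \mu_{ij}/(\mu_{ij}+\phi_i) - y_{ij}}
#' through the factorization; the l1 part contributes `lambda * sign(W)`
#' with the subgradient convention sign(0) = 0. Entries whose log-rate sits
#' on the overflow clamp contribute zero smooth gradient.
#'
#' @inheritParams nb_loglik
#' @param lambda nonnegative penalty.
#' @return list with matrices `dW` (p x K) and `dH` (K x n).
#' @export
objective_gradient <- function(counts, model, depths, phi, lambda,
                               log_mean_bound = 30) {
  counts <- as_count_matrix(counts)
  check_model_dims(counts, model, depths, phi)
  Y <- unclass(counts)
  n <- ncol(Y)
  eta_raw <- model$W %*% model$H
  eta <- clamp(eta_raw, -log_mean_bound, log_mean_bound)
  mu <- exp(sweep(eta, 2L, log(depths), "+"))
  phim <- rep(phi, times = n)
  G <- (Y + phim) * (mu / (mu + phim)) - Y
  if (any(eta_raw != eta)) G[eta_raw != eta] <- 0
  if (!all(is.finite(G)))
    stop("non-finite gradient encountered", call. = FALSE)
  list(dW = G %*% t(model$H) + lambda * sign(model$W),
       dH = crossprod(model$W, G))
}

#' Fit the penalized NB matrix factorization
#'
#' Minimizes `-loglik + lambda * ||W||_1` over (W, H) with full-batch
#' first-order updates (Adam by default, with the canonical moments
#' beta1 = 0.9, beta2 = 0.999, eps = 1e-8), holding the per-gene dispersions
#' and per-cell depth offsets fixed — the two-step procedure: estimate
#' dispersion first, then optimize the factorization.
#'
#' The objective is logged every iteration; the run stops at `max_iter` or
#' as soon as the relative change between consecutive 100-iteration moving
#' averages of the trace drops below `rel_tol`. Adam steps are not
#' individually monotone, but the smoothed trace decreases.
#'
#' @param counts a [count_matrix()].
#' @param depths per-cell depths (default column sums).
#' @param phi per-gene dispersions (default [estimate_dispersion()] followed
#'   by [shrink_dispersion()] with weight 0.2).
#' @param config a [fit_config()].
#' @return a `fit_result` list: `model` ([factor_model()]), `objective_trace`
#'   (one value per iteration, evaluated before that iteration's update),
#'   `n_iter_run`, `converged`.
#' @examples
#' sim <- simulate_counts(sim_config(n_cells = 60, n_genes = 80,
#'                                   n_types = 3, seed = 1))
#' fit <- fit_scnbmf(sim$counts,
#'                   config = fit_config(n_components = 4, max_iter = 200))
#' @export
fit_scnbmf <- function(counts, depths = NULL, phi = NULL,
                       config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  counts <- as_count_matrix(counts)
  Y <- unclass(counts)
  p <- nrow(Y); n <- ncol(Y)
  if (is.null(depths)) depths <- size_factors(counts)
  if (is.null(phi))
    phi <- shrink_dispersion(
      estimate_dispersion(counts, depths, config$phi_min, config$phi_max))
  phi <- clamp(phi, config$phi_min, config$phi_max)
  check_model_dims(counts, factor_model(matrix(0, p, config$n_components),
                                        matrix(0, config$n_components, n)),
                   depths, phi)

  K <- config$n_components
  lambda <- config$lambda
  lr <- config$learning_rate
  bound <- config$log_mean_bound
  init <- init_factors(p, n, K, config$seed)
  W <- init$W; H <- init$H

  # constants of the log-likelihood that do not involve (W, H)
  phim <- matrix(phi, p, n)
  logN <- matrix(log(depths), p, n, byrow = TRUE)
  Yphi <- Y + phim
  const <- sum(lgamma(Yphi) - lgamma(phim) - lgamma(Y + 1)) +
    n * sum(phi * log(phi)) + sum(Y * logN)

  step <- make_optimizer(config$optimizer, lr, p, n, K)
  prox <- config$penalty_method == "proximal"

  trace <- numeric(config$max_iter)
  converged <- FALSE
  t <- 0L
  while (t < config$max_iter) {
    t <- t + 1L
    eta <- W %*% H
    mask <- abs(eta) > bound
    clip <- any(mask)
    if (clip) eta <- clamp(eta, -bound, bound)
    mu <- exp(logN + eta)
    mup <- mu + phim
    obj <- -(sum(Y * eta) + const - sum(Yphi * log(mup))) +
      lambda * sum(abs(W))
    if (!is.finite(obj))
      stop("objective became non-finite at iteration ", t, call. = FALSE)
    trace[t] <- obj

    G <- Yphi * (mu / mup) - Y
    if (clip) G[mask] <- 0
    dW <- G %*% t(H)
    if (!prox && lambda > 0) dW <- dW + lambda * sign(W)
    dH <- crossprod(W, G)
    upd <- step(dW, dH, t)
    W <- W - upd$dW
    H <- H - upd$dH
    if (prox && lambda > 0) {
      thr <- lr * lambda
      W <- sign(W) * pmax(abs(W) - thr, 0)
    }

    if (t %% 100L == 0L && t >= 200L) {
      ma1 <- mean(trace[(t - 99L):t])
      ma0 <- mean(trace[(t - 199L):(t - 100L)])
      if (abs(ma0 - ma1) <= config$rel_tol * abs(ma0)) {
        converged <- TRUE
        break
      }
    }
  }

  structure(list(model = factor_model(W, H),
                 objective_trace = trace[seq_len(t)],
                 n_iter_run = t,
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: K = %d, %d iterations%s, objective %.4g -> %.4g\n",
    x$model$K, x$n_iter_run, if (x$converged) " (converged)" else "",
    x$objective_trace[1L], x$objective_trace[x$n_iter_run]))
  invisible(x)
}

# One first-order update rule; returns function(dW, dH, t) -> list(dW, dH)
# of scaled steps to subtract.
make_optimizer <- function(name, lr, p, n, K) {
  zW <- matrix(0, p, K); zH <- matrix(0, K, n)
  switch(name,
    adam = {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      mW <- zW; vW <- zW; mH <- zH; vH <- zH
      function(dW, dH, t) {
        mW <<- b1 * mW + (1 - b1) * dW
        vW <<- b2 * vW + (1 - b2) * dW^2
        mH <<- b1 * mH + (1 - b1) * dH
        vH <<- b2 * vH + (1 - b2) * dH^2
        c1 <- 1 - b1^t; c2 <- 1 - b2^t
        list(dW = lr * (mW / c1) / (sqrt(vW / c2) + eps),
             dH = lr * (mH / c1) / (sqrt(vH / c2) + eps))
      }
    },
    sgd = function(dW, dH, t) list(dW = lr * dW, dH = lr * dH),
    adagrad = {
      eps <- 1e-8
      gW <- zW; gH <- zH
      function(dW, dH, t) {
        gW <<- gW + dW^2
        gH <<- gH + dH^2
        list(dW = lr * dW / (sqrt(gW) + eps),
             dH = lr * dH / (sqrt(gH) + eps))
      }
    },
    momentum = {
      gamma <- 0.9
      vW <- zW; vH <- zH
      function(dW, dH, t) {
        vW <<- gamma * vW + lr * dW
        vH <<- gamma * vH + lr * dH
        list(dW = vW, dH = vH)
      }
    },
    stop("unknown optimizer: ", name, call. = FALSE))
}
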