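#' Negative binomial log-probability mass
#'
#' Log of the NB pmf in the mean/dispersion parameterization used throughout
#' this package:
#' \deqn{\Pr(y \mid \mu, \phi) = \binom{y+\phi-1}{y}
#'   \left(\frac{\mu}{\mu+\phi}\right)^{y}
#'   \left(\frac{\phi}{\mu+\phi}\right)^{\phi},}
#' evaluated with log-gamma functions so that non-integer \eqn{\phi} is
#' handled exactly. Under this parameterization the variance is
#' \eqn{\mu + \mu^2/\phi}: small \eqn{\phi} means strong over-dispersion and
#' the Poisson distribution is recovered as \eqn{\phi \to \infty}.
#'
#' @param y nonnegative integer counts (vectorized, recycled).
#' @param mu positive means.
#' @param phi positive gene-wise dispersions.
#' @return log-probabilities, `<= 0` up to floating error.
#' @examples
#' nb_logpmf(0, 5, 2)            # 2 * log(2/7)
#' nb_logpmf(4, 2, 1e8)          # ~ dpois(4, 2, log = TRUE)
#' @export
nb_logpmf <- function(y, mu, phi) {
  k <- max(length(y), length(mu), length(phi))
  y <- rep_len(as.numeric(y), k)
  mu <- rep_len(as.numeric(mu), k)
  phi <- rep_len(as.numeric(phi), k)
  if (!all(is.finite(y)) || !all(is.finite(mu)) || !all(is.finite(phi)))
    stop("nb_logpmf: arguments must be finite", call. = FALSE)
  if (any(y < 0) || any(y != floor(y)))
    stop("nb_logpmf: `y` must be nonnegative integers", call. = FALSE)
  if (any(mu <= 0) || any(phi <= 0))
    stop("nb_logpmf: `mu` and `phi` must be positive", call. = FALSE)
  nb_logpmf_unchecked(y, mu, phi)
}

# core formula without argument checks, usable on matrices;
# log1p keeps the phi*log(phi/(mu+phi)) term accurate for huge phi.
nb_logpmf_unchecked <- function(y, mu, phi) {
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    y * (log(mu) - log(mu + phi)) - phi * log1p(mu / phi)
}

#' Expected zero fraction under the NB model
#'
#' Probability that a count is zero, \eqn{\Pr(y = 0) = (\phi/(\mu+\phi))^\phi}.
#' Compared against [observed_zero_fraction()] this diagnoses whether zeros
#' in a data set exceed what NB sampling alone explains (dropout beyond the
#' count model). Strictly decreasing in `mu`; approaches \eqn{e^{-\mu}} as
#' \eqn{\phi \to \infty}.
#'
#' @inheritParams nb_logpmf
#' @return values in \[0, 1\].
#' @export
expected_zero_fraction <- function(mu, phi) {
  k <- max(length(mu), length(phi))
  mu <- rep_len(as.numeric(mu), k); phi <- rep_len(as.numeric(phi), k)
  if (any(!is.finite(mu)) || any(!is.finite(phi)) || any(mu <= 0) || any(phi <= 0))
    stop("expected_zero_fraction: `mu` and `phi` must be positive and finite",
         call. = FALSE)
  exp(-phi * log1p(mu / phi))
}

#' Model log-likelihood over a count matrix
#'
#' Sum over genes and cells of the NB log-pmf with means given by the factor
#' model through the log link with depth offsets,
#' \eqn{\mu_{ij} = N_j e^{\sum_k W_{ik} H_{kj}}}.
#'
#' @param counts a [count_matrix()].
#' @param model a [factor_model()].
#' @param depths per-cell depths N_j ([size_factors()]).
#' @param phi per-gene dispersion vector.
#' @param log_mean_bound clamp on |log(mu/N)| (default 30); hitting it records
#'   a warning.
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(counts, model, depths, phi, log_mean_bound = 30) {
  counts <- as_count_matrix(counts)
  p <- nrow(counts); n <- ncol(counts)
  check_model_dims(counts, model, depths, phi)
  lr <- model_log_rate(model, log_mean_bound)
  if (lr$clipped)
    warning("log-mean clamped to |log(mu/N)| <= ", log_mean_bound)
  mu <- exp(sweep(lr$eta, 2L, log(depths), "+"))
  sum(nb_logpmf_unchecked(unclass(counts), mu, rep(phi, times = n)))
}

#' LASSO-penalized objective (minimization form)
#'
#' The fitting criterion: negative log-likelihood plus an l1 penalty on the
#' gene loadings,
#' \deqn{-\ell(W, H) + \lambda \sum_i \lVert W_i \rVert_1,}
#' so that `lambda = 0` recovers the pure negative log-likelihood and larger
#' `lambda` drives loadings to zero (sparse, interpretable genes).
#'
#' @inheritParams nb_loglik
#' @param lambda nonnegative penalty parameter.
#' @return scalar objective value (to be minimized).
#' @export
penalized_objective <- function(counts, model, depths, phi, lambda,
                                log_mean_bound = 30) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  -nb_loglik(counts, model, depths, phi, log_mean_bound) +
    lambda * sum(abs(model$W))
}

check_model_dims <- function(counts, model, depths, phi) {
  p <- nrow(counts); n <- ncol(counts)
  if (nrow(model$W) != p || ncol(model$H) != n)
    stop("factor model dimensions do not match the count matrix", call. = FALSE)
  if (length(depths) != n || any(!is.finite(depths)) || any(depths <= 0))
    stop("`depths` must be ", n, " positive finite values", call. = FALSE)
  if (length(phi) != p || any(!is.finite(phi)) || any(phi <= 0))
    stop("`phi` must be ", p, " positive finite values", call. = FALSE)
  invisible(TRUE)
}

#' Observed vs NB-expected dropout rates per gene
#'
#' For each gene, the observed zero fraction and the zero fraction expected
#' under the NB model at that gene's mean expression and dispersion. The
#' expected value for gene i averages \eqn{\Pr(y = 0)} over cells, with the
#' per-cell mean scaled by depth: \eqn{\mu_{ij} = m_i N_j / \bar N} where
#' \eqn{m_i} is the depth-normalized mean count. Genes lying far above the
#' expected curve indicate zero inflation the plain NB model cannot absorb.
#'
#' @inheritParams nb_loglik
#' @param phi optional per-gene dispersions; estimated by
#'   [estimate_dispersion()] when missing.
#' @param depths optional depths; column sums when missing.
#' @return data.frame with `gene_id`, `mean_expr` (depth-normalized mean),
#'   `observed`, `expected`.
#' @export
dropout_diagnostic <- function(counts, phi = NULL, depths = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(depths)) depths <- size_factors(counts)
  if (is.null(phi)) phi <- estimate_dispersion(counts, depths)
  p <- nrow(counts); n <- ncol(counts)
  rel <- depths / mean(depths)
  m <- rowMeans(sweep(unclass(counts), 2L, rel, "/"))
  expected <- numeric(p)
  pos <- m > 0
  if (any(pos)) {
    mu <- outer(m[pos], rel)  # per-cell means, depth-scaled
    expected[pos] <- rowMeans(exp(-phi[pos] * log1p(mu / phi[pos])))
  }
  expected[!pos] <- 1
  data.frame(gene_id = rownames(counts), mean_expr = m,
             observed = observed_zero_fraction(counts),
             expected = expected, row.names = NULL)
}
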