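#' Gene-wise over-dispersion by method of moments
#'
#' Estimates the NB dispersion \eqn{\phi_i} of each gene from depth-normalized
#' counts \eqn{\tilde y_{ij} = y_{ij} \bar N / N_j}. Under the model the
#' variance is \eqn{\mu + \mu^2/\phi}, so matching the sample moments gives
#' the plug-in estimator \eqn{\hat\phi_i = m_i^2 / (v_i - m_i)} with sample
#' mean \eqn{m_i} and variance \eqn{v_i}. Genes with \eqn{v_i \le m_i}
#' (Poisson-like or under-dispersed) get `phi_max`; all estimates are clamped
#' to `[phi_min, phi_max]`.
#'
#' Dispersion enters the factorization only as a fixed per-gene nuisance
#' parameter, estimated once before optimizing (W, H).
#'
#' @param counts a [count_matrix()].
#' @param depths per-cell depths (default column sums).
#' @param phi_min,phi_max clamp bounds (defaults 1e-3 and 1e8, a numerically
#'   safe range from near-Poisson to extreme over-dispersion).
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, depths = NULL,
                                phi_min = 1e-3, phi_max = 1e8) {
  counts <- as_count_matrix(counts)
  n <- ncol(counts)
  if (n < 2L) stop("dispersion estimation needs at least 2 cells", call. = FALSE)
  if (is.null(depths)) depths <- size_factors(counts)
  if (length(depths) != n || any(depths <= 0))
    stop("`depths` must be ", n, " positive values", call. = FALSE)
  ytil <- sweep(unclass(counts), 2L, mean(depths) / depths, "*")
  m <- rowMeans(ytil)
  v <- row_vars(ytil)
  phi <- rep(phi_max, nrow(counts))
  over <- v > m & m > 0
  phi[over] <- m[over]^2 / (v[over] - m[over])
  phi <- clamp(phi, phi_min, phi_max)
  names(phi) <- rownames(counts)
  phi
}

#' Shrink dispersion estimates toward their common value
#'
#' Log-space interpolation between each raw estimate and the geometric mean
#' of all estimates:
#' \eqn{\log \hat\phi_i^{shr} = (1-w) \log \hat\phi_i + w \log \bar\phi}.
#' `weight = 0` is the identity; `weight = 1` collapses every gene to the
#' common value. A mild weight stabilizes the noisy per-gene moment estimates
#' in the spirit of empirical-Bayes tagwise shrinkage.
#'
#' @param phi_raw positive per-gene dispersion vector.
#' @param weight shrinkage weight in \[0, 1\] (default 0.2).
#' @return shrunken dispersion vector, names preserved.
#' @export
shrink_dispersion <- function(phi_raw, weight = 0.2) {
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0 || weight > 1)
    stop("`weight` must be a single number in [0, 1]", call. = FALSE)
  if (any(!is.finite(phi_raw)) || any(phi_raw <= 0))
    stop("`phi_raw` must be positive and finite", call. = FALSE)
  lp <- log(phi_raw)
  out <- exp((1 - weight) * lp + weight * mean(lp))
  names(out) <- names(phi_raw)
  out
}
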