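#' Construct a factor model (loadings and factors)
#'
#' Holds the factorization of the log-rate: a genes x K loading matrix W and
#' a K x cells factor matrix H. Together with per-cell depths N_j they define
#' the NB mean through the log link
#' \deqn{\log \mu_{ij} = \log N_j + \sum_k W_{ik} H_{kj}.}
#' The columns of H are the coordinates of the cells in the latent space and
#' are the embedding used for cell-type detection.
#'
#' @param W numeric matrix, genes x K, finite entries (gene loadings; the
#'   object carrying the LASSO penalty).
#' @param H numeric matrix, K x cells, finite entries (cell factors).
#' @return a `factor_model` list with elements `W`, `H`, `K`.
#' @export
factor_model <- function(W, H) {
  if (!is.matrix(W) || !is.matrix(H))
    stop("`W` and `H` must be matrices", call. = FALSE)
  K <- ncol(W)
  if (K < 1L || nrow(H) != K)
    stop("ncol(W) and nrow(H) must agree and be >= 1", call. = FALSE)
  if (K > min(nrow(W), ncol(H)))
    stop("K must not exceed min(genes, cells)", call. = FALSE)
  if (!all(is.finite(W)) || !all(is.finite(H)))
    stop("factor model entries must be finite", call. = FALSE)
  structure(list(W = W, H = H, K = K), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d genes x %d cells, K = %d\n",
              nrow(x$W), ncol(x$H), x$K))
  invisible(x)
}

# Log-rate relative to depth, optionally clamped to avoid overflow in exp().
# Returns list(eta = clamped log(mu/N), clipped = logical any clamping).
model_log_rate <- function(model, log_mean_bound = 30) {
  eta <- model$W %*% model$H
  clipped <- FALSE
  if (any(abs(eta) > log_mean_bound)) {
    eta <- clamp(eta, -log_mean_bound, log_mean_bound)
    clipped <- TRUE
  }
  list(eta = eta, clipped = clipped)
}

#' Fitted NB means of a factor model
#'
#' @param model a [factor_model()].
#' @param depths per-cell depths N_j (see [size_factors()]).
#' @param log_mean_bound clamp on |log(mu/N)| preventing overflow (default 30);
#'   a warning is recorded when the bound is hit.
#' @return genes x cells matrix of positive means.
#' @export
fitted_means <- function(model, depths, log_mean_bound = 30) {
  lr <- model_log_rate(model, log_mean_bound)
  if (lr$clipped)
    warning("log-mean clamped to |log(mu/N)| <= ", log_mean_bound)
  exp(sweep(lr$eta, 2L, log(depths), "+"))
}

#' Order factors by decreasing variance
#'
#' NB factors have no inherent order; for "top m factors" usage the rows of H
#' (and matching columns of W) are permuted by decreasing variance of the H
#' rows, ties broken by original index. Idempotent.
#'
#' @param model a fitted [factor_model()].
#' @return a `factor_model` with permuted components.
#' @export
order_factors <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  v <- row_vars(model$H)
  ord <- order(-v, seq_along(v))
  factor_model(model$W[, ord, drop = FALSE], model$H[ord, , drop = FALSE])
}
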