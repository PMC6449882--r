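#' Simulation configuration
#'
#' Settings for the synthetic count generator. Defaults emulate the
#' structure of small published scRNA-seq cell-type studies: a few hundred
#' cells, 4 planted cell types, NB counts with gene-wise dispersion spanning
#' strong over-dispersion to near-Poisson, log-normal per-cell depths around
#' 5000 reads, and high sparsity.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_types number of planted cell types (default 4).
#' @param k_latent rank of the stored ground-truth factorization; must be
#'   `>= n_types` (extra dimensions are zero rows/columns). Default `n_types`.
#' @param log_fold_scale standard deviation of the per-type gene log-fold
#'   effects (default 1.0, well-separated types; 0 gives no signal at all).
#' @param base_log_mean baseline gene log-expression before per-type shifts
#'   (default `log(2)`).
#' @param phi_levels gene dispersions, cycled across genes
#'   (default `c(0.5, 2, 10)`: strong to mild over-dispersion).
#' @param depth_sd_log sd of log per-cell depth around log(5000)
#'   (default 0.3; 0 gives equal depths).
#' @param type_proportions optional simplex vector of length `n_types`;
#'   uniform when `NULL`.
#' @param dropout_rate extra probability of zeroing any entry, for
#'   robustness experiments only (default 0: plain NB, no zero inflation).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 300L, n_genes = 500L, n_types = 4L,
                       k_latent = n_types, log_fold_scale = 1.0,
                       base_log_mean = log(2), phi_levels = c(0.5, 2, 10),
                       depth_sd_log = 0.3, type_proportions = NULL,
                       dropout_rate = 0, seed = 1L) {
  n_cells <- as.integer(n_cells); n_genes <- as.integer(n_genes)
  n_types <- as.integer(n_types); k_latent <- as.integer(k_latent)
  if (n_cells < 1L || n_genes < 1L || n_types < 1L)
    stop("dimensions must be positive", call. = FALSE)
  if (n_types > n_cells) stop("`n_types` must not exceed `n_cells`", call. = FALSE)
  if (k_latent < n_types)
    stop("`k_latent` must be >= `n_types`", call. = FALSE)
  if (log_fold_scale < 0 || depth_sd_log < 0 || dropout_rate < 0 ||
      dropout_rate >= 1)
    stop("scale parameters out of range", call. = FALSE)
  if (any(phi_levels <= 0)) stop("`phi_levels` must be positive", call. = FALSE)
  if (is.null(type_proportions)) {
    type_proportions <- rep(1 / n_types, n_types)
  } else {
    if (length(type_proportions) != n_types || any(type_proportions <= 0))
      stop("`type_proportions` must be ", n_types, " positive values",
           call. = FALSE)
    type_proportions <- type_proportions / sum(type_proportions)
  }
  structure(list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
                 k_latent = k_latent, log_fold_scale = log_fold_scale,
                 base_log_mean = base_log_mean, phi_levels = phi_levels,
                 depth_sd_log = depth_sd_log,
                 type_proportions = type_proportions,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate counts with planted cell types
#'
#' Draws data exactly from the model class the factorization assumes, so
#' parameter and cluster recovery are a fair benchmark. Each cell type t has
#' a gene log-fold vector \eqn{\Delta_{\cdot t} \sim N(0,
#' \texttt{log\_fold\_scale}^2)}; per-cell depths are
#' \eqn{N_j = \mathrm{round}(\mathrm{lognormal}(\log 5000,
#' \texttt{depth\_sd\_log}))}; dispersions cycle through `phi_levels`; and
#' \deqn{y_{ij} \sim NB\!\left(N_j \frac{e^{b + \Delta_{i,type(j)}}}{c_{type(j)}},\ \phi_i\right)}
#' with the per-type normalizer \eqn{c_t = \sum_i e^{b + \Delta_{it}}} making
#' expected column sums equal the drawn depths. Cells are assigned to types
#' in the configured proportions (every type is always present).
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]), `labels` (integer type
#'   per cell) and `truth` (`W_true` p x k_latent, `H_true` k_latent x n
#'   one-hot, `phi_true`, `depths_true`); `W_true %*% H_true` reproduces
#'   `log(mu/N)` exactly.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_genes; n <- config$n_cells; Tt <- config$n_types
  with_seed(config$seed, {
    # type assignment honoring the proportions, all types present
    base_counts <- floor(config$type_proportions * n)
    rem <- n - sum(base_counts)
    if (rem > 0) {
      extra <- order(config$type_proportions * n - base_counts,
                     decreasing = TRUE)[seq_len(rem)]
      base_counts[extra] <- base_counts[extra] + 1L
    }
    base_counts <- pmax(base_counts, 1L)
    while (sum(base_counts) > n)
      base_counts[which.max(base_counts)] <- base_counts[which.max(base_counts)] - 1L
    labels <- sample(rep(seq_len(Tt), times = base_counts))

    delta <- matrix(stats::rnorm(p * Tt, 0, config$log_fold_scale), p, Tt)
    logshare <- config$base_log_mean + delta
    logshare <- sweep(logshare, 2L, log(colSums(exp(logshare))), "-")

    depths <- pmax(1, round(stats::rlnorm(n, log(5000), config$depth_sd_log)))
    phi <- rep_len(config$phi_levels, p)

    mu <- exp(logshare[, labels, drop = FALSE])  # shares per cell
    mu <- sweep(mu, 2L, depths, "*")
    y <- stats::rnbinom(p * n, size = rep(phi, times = n), mu = as.vector(mu))
    if (config$dropout_rate > 0)
      y[stats::runif(p * n) < config$dropout_rate] <- 0L
    Y <- matrix(as.numeric(y), p, n)

    W_true <- cbind(logshare,
                    matrix(0, p, config$k_latent - Tt))
    H_true <- matrix(0, config$k_latent, n)
    H_true[cbind(labels, seq_len(n))] <- 1

    list(counts = count_matrix(Y),
         labels = as.integer(labels),
         truth = list(W_true = W_true, H_true = H_true,
                      phi_true = phi, depths_true = as.numeric(depths)))
  })
}
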