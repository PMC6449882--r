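#' Normalized mutual information between two labelings
#'
#' \deqn{NMI(L_e, L) = \frac{I(L_e; L)}{\sqrt{H(L_e) H(L)}}}
#' computed from the contingency counts of the two partitions. Symmetric,
#' invariant to label renaming, in \[0, 1\]; 1 iff the partitions coincide up
#' to renaming. When either partition has zero entropy (a single cluster) the
#' value is defined as 0, except when both are single-cluster — then the
#' partitions are identical and the value is 1.
#'
#' @param labels_pred,labels_true vectors of equal length (any atomic type;
#'   treated as categorical).
#' @return scalar in \[0, 1\].
#' @export
nmi <- function(labels_pred, labels_true) {
  if (length(labels_pred) != length(labels_true))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labels_pred)
  if (n < 1L) stop("labels must be nonempty", call. = FALSE)
  tab <- table(labels_pred, labels_true)
  pk <- rowSums(tab) / n
  pt <- colSums(tab) / n
  hk <- -sum(pk * log(pk))
  ht <- -sum(pt * log(pt))
  if (hk == 0 && ht == 0) return(1)
  if (hk == 0 || ht == 0) return(0)
  joint <- tab / n
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / (pk %o% pt)[nz]))
  min(max(mi / sqrt(hk * ht), 0), 1)
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement corrected for chance:
#' \deqn{ARI = \frac{\sum_{kt}\binom{n_{kt}}{2} - E}
#'   {\tfrac12\left[\sum_k\binom{n_k}{2}+\sum_t\binom{n_t}{2}\right] - E},
#'   \quad E = \frac{\sum_k\binom{n_k}{2}\sum_t\binom{n_t}{2}}{\binom{n}{2}}.}
#' Equals 1 for identical partitions, is near 0 for independent ones and can
#' be negative. Symmetric and invariant to label renaming.
#'
#' @inheritParams nmi
#' @return scalar `<= 1`.
#' @export
ari <- function(labels_pred, labels_true) {
  if (length(labels_pred) != length(labels_true))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labels_pred)
  if (n < 2L) stop("ARI needs at least 2 observations", call. = FALSE)
  tab <- table(labels_pred, labels_true)
  sij <- sum(choose(tab, 2))
  sk <- sum(choose(rowSums(tab), 2))
  st <- sum(choose(colSums(tab), 2))
  # rescaled by choose(n, 2) so all terms stay integer-exact in doubles
  tot <- choose(n, 2)
  num <- tot * sij - sk * st
  denom <- tot * (sk + st) / 2 - sk * st
  if (denom == 0) return(1)  # both partitions degenerate and identical
  num / denom
}

#' log2 transform with pseudo-count 1
#'
#' The normalization convention used when handing counts to methods that
#' expect continuous data: elementwise `log2(y + 1)`. The NB factorization
#' itself works on raw counts and never needs this.
#'
#' @param counts a [count_matrix()] or numeric matrix.
#' @return numeric matrix of the same shape, dimnames preserved.
#' @export
log2_pseudocount_transform <- function(counts) {
  x <- if (inherits(counts, "count_matrix")) unclass(counts) else
    as.matrix(counts)
  log2(x + 1)
}

#' Repeated k-means scoring of an embedding
#'
#' The evaluation protocol: run k-means (Lloyd iterations from k-means++
#' starts) on the cells as points in factor space, repeated `n_repeats`
#' times with seeds `seed .. seed + n_repeats - 1`, and score every repeat
#' against the true labels with [nmi()] and [ari()].
#'
#' @param factors K x cells numeric matrix (rows of H; cells are points in
#'   K-dimensional space).
#' @param labels_true true labels, one per cell.
#' @param n_clusters number of clusters; defaults to the number of distinct
#'   true labels.
#' @param n_repeats number of k-means restarts (default 100).
#' @param seed base RNG seed.
#' @return a `clustering_result` list: `per_repeat_nmi`, `per_repeat_ari`,
#'   `mean_nmi`, `best_nmi`, `mean_ari`, `best_ari`, `n_repeats`,
#'   `labels_best` (assignment of the repeat with the highest ARI).
#' @export
cluster_and_score <- function(factors, labels_true, n_clusters = NULL,
                              n_repeats = 100L, seed = 1L) {
  factors <- as.matrix(factors)
  n <- ncol(factors)
  if (length(labels_true) != n)
    stop("`labels_true` must have one entry per cell (column)", call. = FALSE)
  if (is.null(n_clusters)) n_clusters <- length(unique(labels_true))
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 2L) stop("`n_clusters` must be >= 2", call. = FALSE)
  if (n_clusters > n) stop("`n_clusters` exceeds the number of cells", call. = FALSE)
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1", call. = FALSE)
  x <- t(factors)
  nmis <- numeric(n_repeats); aris <- numeric(n_repeats)
  labels_best <- NULL; best <- -Inf
  for (r in seq_len(n_repeats)) {
    km <- with_seed(seed + r - 1L, {
      centers <- kmeanspp_centers(x, n_clusters)
      suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 200L,
                      algorithm = "Lloyd"))
    })
    nmis[r] <- nmi(km$cluster, labels_true)
    aris[r] <- ari(km$cluster, labels_true)
    if (aris[r] > best) { best <- aris[r]; labels_best <- km$cluster }
  }
  structure(list(per_repeat_nmi = nmis, per_repeat_ari = aris,
                 mean_nmi = mean(nmis), best_nmi = max(nmis),
                 mean_ari = mean(aris), best_ari = max(aris),
                 n_repeats = as.integer(n_repeats),
                 labels_best = unname(labels_best)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "clustering_result over %d k-means repeats:\n  NMI mean %.4f best %.4f\n  ARI mean %.4f best %.4f\n",
    x$n_repeats, x$mean_nmi, x$best_nmi, x$mean_ari, x$best_ari))
  invisible(x)
}

# k-means++ seeding: first center uniform, each next drawn with probability
# proportional to squared distance to the nearest chosen center. Zero-distance
# points get probability zero, so chosen centers are distinct whenever the
# data contain enough distinct points.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      pool <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- pool[sample.int(length(pool), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ], "-")^2))
  }
  x[idx, , drop = FALSE]
}
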