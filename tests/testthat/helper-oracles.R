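# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# NB log-pmf oracle: stats::dnbinom in the size/mu parameterization is the
# same pmf with size = phi.
oracle_nb_logpmf <- function(y, mu, phi) {
  stats::dnbinom(y, size = phi, mu = mu, log = TRUE)
}

# Brute-force NMI straight from the entropy definitions, loops and all.
oracle_nmi <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      px <- sum(a == x) / n
      py <- sum(b == y) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  ha <- -sum(vapply(ua, function(x) {
    px <- sum(a == x) / n; px * log(px)
  }, numeric(1)))
  hb <- -sum(vapply(ub, function(y) {
    py <- sum(b == y) / n; py * log(py)
  }, numeric(1)))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}

# Brute-force ARI by enumerating all pairs of observations: counts pairs
# co-clustered in both / one / neither partition, then the 2x2 association
# form of the adjusted index.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

random_label_pair <- function(n = 50, max_k = 6) {
  list(a = sample.int(sample(2:max_k, 1), n, replace = TRUE),
       b = sample.int(sample(2:max_k, 1), n, replace = TRUE))
}

# Small random model instance for gradient / likelihood checks; loadings are
# kept away from zero so the l1 subgradient is smooth at the test point.
random_instance <- function(p = 8, n = 6, K = 2, seed = 1) {
  set.seed(seed)
  Y <- matrix(rpois(p * n, 4), p, n)
  Y[1, 1] <- Y[1, 1] + 1  # guard against an all-zero cell
  W <- matrix(rnorm(p * K, 0, 0.05), p, K)
  W <- sign(W) * pmax(abs(W), 1e-3)
  H <- matrix(rnorm(K * n, 0, 0.05), K, n)
  list(counts = count_matrix(Y), model = factor_model(W, H),
       depths = colSums(Y), phi = runif(p, 0.5, 5))
}

# Central finite differences of the penalized objective in every coordinate.
numeric_gradient <- function(inst, lambda, h = 1e-5) {
  f <- function(W, H) penalized_objective(
    inst$counts, factor_model(W, H), inst$depths, inst$phi, lambda)
  W <- inst$model$W; H <- inst$model$H
  dW <- W * 0; dH <- H * 0
  for (i in seq_along(W)) {
    Wp <- W; Wm <- W
    Wp[i] <- W[i] + h; Wm[i] <- W[i] - h
    dW[i] <- (f(Wp, H) - f(Wm, H)) / (2 * h)
  }
  for (i in seq_along(H)) {
    Hp <- H; Hm <- H
    Hp[i] <- H[i] + h; Hm[i] <- H[i] - h
    dH[i] <- (f(W, Hp) - f(W, Hm)) / (2 * h)
  }
  list(dW = dW, dH = dH)
}
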