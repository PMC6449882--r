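test_that("nb_logpmf matches closed forms and the reference pmf", {
  # at y = 0 only the (phi/(mu+phi))^phi factor survives
  expect_equal(nb_logpmf(0, 5, 2), 2 * log(2 / 7), tolerance = 1e-12)
  expect_equal(nb_logpmf(2, 3, 1.5), oracle_nb_logpmf(2, 3, 1.5),
               tolerance = 1e-12)
  set.seed(42)
  y <- rpois(500, 10)
  mu <- runif(500, 0.05, 50)
  phi <- exp(runif(500, log(0.01), log(100)))
  expect_lt(max(abs(nb_logpmf(y, mu, phi) - oracle_nb_logpmf(y, mu, phi))),
            1e-10)
  expect_true(all(nb_logpmf(y, mu, phi) <= 1e-12))
})

test_that("nb_logpmf rejects out-of-domain arguments", {
  expect_error(nb_logpmf(-1, 2, 1), "nonnegative")
  expect_error(nb_logpmf(1.5, 2, 1), "nonnegative integers")
  expect_error(nb_logpmf(1, -2, 1), "positive")
  expect_error(nb_logpmf(1, 2, 0), "positive")
  expect_error(nb_logpmf(1, Inf, 1), "finite")
})

test_that("probabilities sum to one over the count support", {
  set.seed(7)
  for (i in 1:20) {
    mu <- runif(1, 0.2, 20)
    phi <- exp(runif(1, log(0.05), log(50)))
    # truncate where the NB upper tail drops below 1e-12; heavy-tailed for
    # small phi, so a quantile-based cut is needed rather than mean + k*sd
    ymax <- qnbinom(1e-12, size = phi, mu = mu, lower.tail = FALSE) + 10
    total <- sum(exp(nb_logpmf(0:ymax, mu, phi)))
    expect_lt(abs(total - 1), 1e-8)
  }
})

test_that("large-dispersion limit is Poisson", {
  expect_equal(nb_logpmf(4, 2, 1e8), dpois(4, 2, log = TRUE),
               tolerance = 1e-3)
})

test_that("simulated draws obey the NB mean-variance law", {
  set.seed(11)
  y <- rnbinom(1e5, size = 2, mu = 5)
  se <- sqrt((5 + 25 / 2) / 1e5)
  expect_lt(abs(mean(y) - 5), 3 * se)
  expect_lt(abs(var(y) - (5 + 25 / 2)) / (5 + 25 / 2), 0.05)
})

test_that("expected zero fraction has the right values and limits", {
  expect_equal(expected_zero_fraction(2, 1), 1 / 3, tolerance = 1e-12)
  expect_gt(expected_zero_fraction(1e-9, 2), 1 - 1e-6)
  expect_equal(expected_zero_fraction(2, 1e8), exp(-2), tolerance = 1e-4)
  # strictly decreasing in mu at fixed phi
  mus <- seq(0.1, 20, length.out = 50)
  expect_true(all(diff(expected_zero_fraction(mus, 2)) < 0))
  expect_equal(expected_zero_fraction(mus, 1e9), exp(-mus), tolerance = 1e-6)
  expect_error(expected_zero_fraction(-1, 2), "positive")
})

test_that("nb_loglik is the elementwise sum of nb_logpmf", {
  # offset-only model: mu_ij = N_j
  Y <- count_matrix(rbind(c(1, 0), c(2, 3)))
  model0 <- factor_model(matrix(0, 2, 1), matrix(0, 1, 2))
  depths <- c(3, 3); phi <- c(1, 1)
  manual <- sum(oracle_nb_logpmf(c(1, 2, 0, 3), rep(3, 4), rep(1, 4)))
  expect_equal(nb_loglik(Y, model0, depths, phi), manual, tolerance = 1e-12)

  for (s in 1:10) {
    inst <- random_instance(p = 7, n = 5, K = 2, seed = s)
    mu <- fitted_means(inst$model, inst$depths)
    manual <- sum(nb_logpmf(as.vector(unclass(inst$counts)), as.vector(mu),
                            rep(inst$phi, times = 5)))
    expect_equal(nb_loglik(inst$counts, inst$model, inst$depths, inst$phi),
                 manual, tolerance = 1e-10)
  }
})

test_that("extreme log-rates are clamped with a warning", {
  Y <- count_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  big <- factor_model(matrix(40, 2, 1), matrix(1, 1, 2))
  expect_warning(ll <- nb_loglik(Y, big, c(3, 7), c(1, 1)), "clamped")
  expect_true(is.finite(ll))
})

test_that("penalized objective adds the l1 term correctly", {
  inst <- random_instance(seed = 3)
  ll <- nb_loglik(inst$counts, inst$model, inst$depths, inst$phi)
  expect_equal(
    penalized_objective(inst$counts, inst$model, inst$depths, inst$phi, 0),
    -ll, tolerance = 1e-12)
  # manual l1 accumulation
  l1 <- sum(abs(as.vector(inst$model$W)))
  expect_equal(
    penalized_objective(inst$counts, inst$model, inst$depths, inst$phi, 2),
    -ll + 2 * l1, tolerance = 1e-10)
  # scaled so the penalty sums to exactly 3.5
  W2 <- inst$model$W * (3.5 / l1)
  m2 <- factor_model(W2, inst$model$H)
  ll2 <- nb_loglik(inst$counts, m2, inst$depths, inst$phi)
  expect_equal(
    penalized_objective(inst$counts, m2, inst$depths, inst$phi, 2),
    -ll2 + 7.0, tolerance = 1e-10)
  # nondecreasing in lambda
  objs <- vapply(c(0, 0.5, 1, 5), function(l)
    penalized_objective(inst$counts, inst$model, inst$depths, inst$phi, l),
    numeric(1))
  expect_true(all(diff(objs) >= 0))
  expect_error(
    penalized_objective(inst$counts, inst$model, inst$depths, inst$phi, -1),
    "nonnegative")
})

test_that("dropout diagnostic compares observed and NB-expected zeros", {
  sim <- simulate_counts(sim_config(n_cells = 150, n_genes = 200,
                                    n_types = 3, seed = 5))
  d <- dropout_diagnostic(sim$counts, phi = sim$truth$phi_true,
                          depths = sim$truth$depths_true)
  expect_named(d, c("gene_id", "mean_expr", "observed", "expected"))
  expect_true(all(d$observed >= 0 & d$observed <= 1))
  expect_true(all(d$expected >= 0 & d$expected <= 1))
  # expectation tracks observation when the generator matches the model
  expect_lt(mean(abs(d$observed - d$expected)), 0.05)
})
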