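test_that("factor initialization is reproducible and correctly scaled", {
  a <- init_factors(50, 40, 5, seed = 11)
  b <- init_factors(50, 40, 5, seed = 11)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
  c_ <- init_factors(50, 40, 5, seed = 12)
  expect_false(identical(a$W, c_$W))
  big <- init_factors(120, 100, 10, seed = 1)
  sd_emp <- sd(c(big$W, big$H))
  expect_lt(abs(sd_emp - 0.01 / sqrt(10)) / (0.01 / sqrt(10)), 0.2)
  expect_error(init_factors(5, 4, 6), "min\\(p, n\\)")
})

test_that("gradient vanishes when fitted means equal the data", {
  depths <- c(3, 7, 2)
  Y <- count_matrix(matrix(rep(depths, each = 4), 4, 3))
  model <- factor_model(matrix(0, 4, 2), matrix(0, 2, 3))
  g <- objective_gradient(Y, model, depths, phi = rep(2, 4), lambda = 0)
  expect_equal(max(abs(g$dW)), 0)
  expect_equal(max(abs(g$dH)), 0)
})

test_that("analytic gradient matches central finite differences", {
  for (s in 1:5) {
    inst <- random_instance(p = 8, n = 6, K = 2, seed = 100 + s)
    for (lambda in c(0, 1)) {
      ana <- objective_gradient(inst$counts, inst$model, inst$depths,
                                inst$phi, lambda)
      num <- numeric_gradient(inst, lambda)
      relW <- sqrt(sum((ana$dW - num$dW)^2)) / sqrt(sum(num$dW^2))
      relH <- sqrt(sum((ana$dH - num$dH)^2)) / sqrt(sum(num$dH^2))
      expect_lt(relW, 1e-4)
      expect_lt(relH, 1e-4)
    }
  }
})

test_that("l1 subgradient is zero at zero loadings", {
  inst <- random_instance(seed = 9)
  W0 <- inst$model$W; W0[1, 1] <- 0
  m0 <- factor_model(W0, inst$model$H)
  g1 <- objective_gradient(inst$counts, m0, inst$depths, inst$phi, 0)
  g2 <- objective_gradient(inst$counts, m0, inst$depths, inst$phi, 5)
  # penalty contributes nothing at the zero entry, lambda*sign elsewhere
  expect_equal(g2$dW[1, 1], g1$dW[1, 1])
  expect_equal(g2$dW[2, 1], g1$dW[2, 1] + 5 * sign(W0[2, 1]))
})

test_that("fitting reduces the objective substantially on planted data", {
  sim <- simulate_counts(sim_config(n_cells = 200, n_genes = 300,
                                    n_types = 3, seed = 7))
  fit <- fit_scnbmf(sim$counts,
                    config = fit_config(n_components = 5, lambda = 1,
                                        max_iter = 1500, seed = 7))
  first <- fit$objective_trace[1]
  last <- fit$objective_trace[fit$n_iter_run]
  expect_lt(last, 0.9 * first)
  # smoothed trace is non-increasing even though Adam steps are not
  ma <- stats::filter(fit$objective_trace, rep(1 / 100, 100), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-8 * abs(ma[-length(ma)])))
})

test_that("fits are deterministic for a fixed seed", {
  sim <- simulate_counts(sim_config(n_cells = 60, n_genes = 80,
                                    n_types = 3, seed = 2))
  cfg <- fit_config(n_components = 3, max_iter = 150, seed = 5)
  f1 <- fit_scnbmf(sim$counts, config = cfg)
  f2 <- fit_scnbmf(sim$counts, config = cfg)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$model$H, f2$model$H)
})

test_that("a single near-zero step leaves the initialization unchanged", {
  sim <- simulate_counts(sim_config(n_cells = 30, n_genes = 40,
                                    n_types = 2, seed = 3))
  cfg <- fit_config(n_components = 2, learning_rate = 1e-12, max_iter = 1,
                    seed = 8)
  fit <- fit_scnbmf(sim$counts, config = cfg)
  init <- init_factors(40, 30, 2, seed = 8)
  expect_equal(fit$n_iter_run, 1L)
  expect_lt(max(abs(fit$model$W - init$W)), 1e-9)
  expect_lt(max(abs(fit$model$H - init$H)), 1e-9)
})

test_that("alternative optimizers run and also descend", {
  sim <- simulate_counts(sim_config(n_cells = 50, n_genes = 60,
                                    n_types = 2, seed = 4))
  for (opt in c("sgd", "adagrad", "momentum")) {
    cfg <- fit_config(n_components = 2, max_iter = 100, seed = 4,
                      learning_rate = if (opt == "sgd") 1e-6 else 1e-3,
                      optimizer = opt)
    fit <- fit_scnbmf(sim$counts, config = cfg)
    expect_lt(fit$objective_trace[fit$n_iter_run], fit$objective_trace[1])
  }
})

test_that("proximal penalty handling produces exact zeros", {
  sim <- simulate_counts(sim_config(n_cells = 50, n_genes = 60,
                                    n_types = 2, seed = 6))
  cfg <- fit_config(n_components = 3, lambda = 10, max_iter = 400, seed = 6,
                    penalty_method = "proximal")
  fit <- fit_scnbmf(sim$counts, config = cfg)
  expect_gt(sum(fit$model$W == 0), 0)
})

test_that("factors are ordered by decreasing variance of H rows", {
  set.seed(13)
  W <- matrix(rnorm(12), 4, 3)
  H <- rbind(rnorm(6, 0, sqrt(0.1)), rnorm(6, 0, sqrt(3)), rnorm(6, 0, 1))
  m <- factor_model(W, H)
  v <- apply(H, 1, var)
  ord <- order(-v)
  m2 <- order_factors(m)
  expect_equal(m2$H, H[ord, ])
  expect_equal(m2$W, W[, ord])
  # idempotent
  m3 <- order_factors(m2)
  expect_identical(m3$H, m2$H)
  # property: non-increasing row variances
  for (s in 1:10) {
    set.seed(s)
    mm <- order_factors(factor_model(matrix(rnorm(40), 10, 4),
                                     matrix(rnorm(32), 4, 8)))
    expect_true(all(diff(apply(mm$H, 1, var)) <= 1e-12))
  }
})
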