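test_that("beta-weight has the right fixed points and bounds", {
  expect_equal(beta_weight(2.5, 2.5, 0.7, 0.2), 1)
  expect_equal(beta_weight(5, 5, 123, 0.9), 1)
  expect_equal(beta_weight(3, 0, 1, 0), 1)
  ## residual constructed so the exponent is exactly -1
  sigma <- 0.8; beta <- 0.2
  d <- sqrt(2 * sigma^2 / beta)
  expect_equal(beta_weight(d, 0, sigma, beta), exp(-1))
  expect_error(beta_weight(1, 0, 0, 0.2), "sigma")
})

test_that("beta-weight strictly decreases in the absolute residual", {
  resid <- seq(0, 6, by = 0.25)
  w <- beta_weight(resid, 0, 1.3, 0.2)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_equal(beta_weight(-resid, 0, 1.3, 0.2), w)  # symmetry
})

test_that("beta = 0 estimation reduces to maximum likelihood", {
  set.seed(21)
  cfg0 <- beta_config(beta = 0)
  for (i in 1:10) {
    d <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 2))
    est <- minimum_beta_divergence_estimate(d, cfg0)
    expect_equal(est$mu, mean(d), tolerance = 1e-10)
    ## the beta-divergence limit is the true (divisor-n) Gaussian MLE of the
    ## variance; the n-1 form of mle_estimate differs by the known factor
    expect_equal(est$sigma^2, sum((d - mean(d))^2) / length(d),
                 tolerance = 1e-10)
    expect_true(all(est$weights == 1))
  }
})

test_that("symmetric data have a robust location fixed at zero", {
  for (b in c(0.1, 0.2, 0.5)) {
    est <- minimum_beta_divergence_estimate(c(-1, 0, 1), beta_config(beta = b))
    expect_equal(est$mu, 0, tolerance = 1e-8)
  }
})

test_that("robust fit attains the grid-search minimum with an injected outlier", {
  d <- c(0.9, 1.0, 1.1, 20)
  est <- minimum_beta_divergence_estimate(d, beta_config())
  oracle <- grid_search_dpd(d, 0.2)
  expect_lt(abs(est$mu - oracle$mu), 0.05)
  obj_fit <- beta_divergence_objective(d, est$mu, est$sigma^2, 0.2)
  expect_lte(obj_fit, oracle$obj + 1e-6)
})

test_that("robust location resists arbitrarily large single outliers", {
  set.seed(22)
  clean <- rnorm(4, 1, 0.2)
  for (M in c(1e3, 1e6)) {
    d <- c(clean, M)
    est <- minimum_beta_divergence_estimate(d, beta_config())
    expect_lt(abs(est$mu - mean(clean)), 3 * sd(clean))
    ## while the MLE mean diverges linearly in M
    expect_gt(mle_estimate(d)$mu, M / length(d) - 1)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(minimum_beta_divergence_estimate(c(2, 2, 2)), "degenerate")
  expect_error(minimum_beta_divergence_estimate(1), "n >= 2")
})

test_that("delta cutoff follows the interpolation rule and cap", {
  expect_equal(delta_cutoff(rep(0.9, 5)), 0.2)          # cap binds
  expect_equal(delta_cutoff(c(0.05, 0.5, 0.95)), 0.14)  # 0.05 + 0.1 * 0.9
  expect_equal(delta_cutoff(c(0, 0)), 0)                # degenerate pool
  expect_error(delta_cutoff(numeric(0)), "empty")
  expect_error(delta_cutoff(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene outlier calls use <= delta, boundary inclusive", {
  expect_false(classify_gene(c(0.8, 0.9, 0.7), 0.2))
  expect_true(classify_gene(c(0.8, 0.1, 0.9), 0.2))
  expect_true(classify_gene(c(0.2, 0.9, 0.9), 0.2))
})

test_that("weight matrix evaluates the weight function at the robust fit", {
  d <- matrix(c(0, 0.1, -0.1), 1, 3)
  wm <- compute_weight_matrix(d, beta_config())
  direct <- beta_weight(d[1, ], wm$mu[1], wm$sigma[1], 0.2)
  expect_equal(wm$weights[1, ], direct)
  expect_true(all(wm$weights[1, ] > 0.85))
  expect_equal(wm$smallest_per_gene[1], min(wm$weights[1, ]))
})

test_that("a tight symmetric genome has all smallest weights above delta", {
  set.seed(23)
  G <- 400
  d <- matrix(rnorm(G * 3, 0, 0.05), G, 3)
  wm <- compute_weight_matrix(d, beta_config())
  expect_lte(wm$delta, 0.2)
  expect_gt(mean(wm$smallest_per_gene > wm$delta), 0.99)
})

test_that("permuting gene order permutes the weight rows identically", {
  set.seed(24)
  d <- matrix(rnorm(60), 20, 3)
  wm <- compute_weight_matrix(d, beta_config())
  perm <- sample(20)
  wm_p <- compute_weight_matrix(d[perm, ], beta_config())
  expect_equal(wm_p$weights, wm$weights[perm, ])
  expect_equal(wm_p$delta, wm$delta)
})

test_that("unification picks the classical branch for clean genes and the robust one otherwise", {
  set.seed(25)
  d <- c(0.9, 1.0, 1.1, 20)
  classical <- mle_estimate(d)
  robust <- minimum_beta_divergence_estimate(d)
  u_clean <- unify_estimates(classical, robust, FALSE)
  expect_identical(u_clean$mu, classical$mu)
  expect_identical(u_clean$kind, "classical")
  u_out <- unify_estimates(classical, robust, TRUE)
  expect_identical(u_out$mu, robust$mu)
  expect_identical(u_out$kind, "robust")
})

test_that("an uncontaminated simulated genome takes the classical branch almost everywhere", {
  sim <- simulate_paired_expression(
    simulation_config(n_genes = 2000, n = 3, seed = 26, contamination = "none"))
  d <- as.matrix(compute_differences(sim$data)[, -1])
  wm <- compute_weight_matrix(d, beta_config())
  expect_gt(mean(!wm$is_outlying_gene), 0.95)
})
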