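test_that("s0 selection breaks exact ties to the smallest candidate", {
  s <- rep(0.5, 40)
  r <- rep(1.2, 40)
  sel <- select_s0(s, r, method = "simple")
  expect_equal(sel$s0, 0.5)  # all percentiles of a constant vector coincide
  expect_equal(sel$s0, sel$candidate_grid$value[1])
})

test_that("near-zero denominators drive the chosen s0 above zero", {
  ## constructed toy: half the genes have tiny scale, which inflates the
  ## spread of u at s0 = 0; brute-force CV over the same grid is the oracle
  set.seed(31)
  s <- c(rep(1e-4, 50), runif(50, 0.5, 1))
  r <- rnorm(100, 2, 0.3)
  sel <- select_s0(s, r, method = "simple")
  cands <- unname(quantile(s, seq(0, 1, 0.05)))
  cv_brute <- sapply(cands, function(s0) {
    u <- r / (s + s0)
    sd(u) / abs(mean(u))
  })
  expect_gt(sel$s0, 0)
  expect_equal(sel$s0, cands[which.min(cv_brute)])
  ## argmin contract
  expect_equal(min(sel$cv_values), sel$cv_values[match(sel$s0, sel$candidate_grid$value)])
})

test_that("windowed-MAD s0 selection satisfies its argmin contract", {
  set.seed(32)
  s <- rexp(500, 5) + 1e-3
  r <- rnorm(500, 0, 0.2 + s)
  sel <- select_s0(s, r, method = "mad_window")
  expect_true(sel$s0 %in% sel$candidate_grid$value)
  expect_equal(sel$cv_values[match(sel$s0, sel$candidate_grid$value)],
               min(sel$cv_values[is.finite(sel$cv_values)]))
  expect_error(select_s0(rep(0, 10), rnorm(10)), "positive scale")
})

test_that("the beta-SAM statistic is the moderated ratio", {
  expect_equal(beta_sam_statistic(2, 1, 4, 0), 4)
  expect_equal(beta_sam_statistic(2, 1, 4, 0.5), 2)
  expect_error(beta_sam_statistic(1, 0, 4, 0), "zero denominator")
  ## vectorised
  expect_equal(beta_sam_statistic(c(1, 2), c(1, 1), 4, 0.5), c(1, 2))
})

test_that("beta-FC takes the mean for clean genes and the robust centre for outliers", {
  expect_equal(beta_fc(mle_estimate(c(1, 2, 3)),
                       minimum_beta_divergence_estimate(c(1, 2, 3)),
                       FALSE), 2)
  d <- c(0.9, 1.0, 1.1, 20)
  fc <- beta_fc(mle_estimate(d), minimum_beta_divergence_estimate(d), TRUE)
  oracle <- grid_search_dpd(d, 0.2)
  expect_lt(abs(fc - oracle$mu), 0.05)
  expect_gt(abs(mean(d) - fc), 4)  # robust branch is far from the raw mean
  ## beta = 0: classical mean for every gene regardless of flag
  est0 <- minimum_beta_divergence_estimate(d, beta_config(beta = 0))
  expect_equal(beta_fc(mle_estimate(d), est0, TRUE), mean(d))
})

test_that("exhaustive sign-flip p-values match single-gene enumeration", {
  ## one gene, d = (c, c, c): the null statistic is recomputed for all 8 sign
  ## patterns through the same unified estimator, independently re-coded here
  ## from the public single-gene operations
  c_val <- 1
  d <- c(c_val, c_val, c_val)
  s0 <- 0.5
  delta <- 0.2
  cfg <- beta_config()
  u_obs <- c_val / s0  # constant gene: classical branch, sigma = 0
  patterns <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
  null_u <- apply(patterns, 1, function(s) {
    ds <- d * as.numeric(s)
    if (diff(range(ds)) == 0) {
      est_mu <- mean(ds); est_sigma <- 0; flagged <- FALSE
    } else {
      rob <- minimum_beta_divergence_estimate(ds, cfg)
      flagged <- classify_gene(rob$weights, delta)
      cls <- mle_estimate(ds)
      uni <- unify_estimates(cls, rob, flagged)
      est_mu <- uni$mu; est_sigma <- uni$sigma
    }
    beta_sam_statistic(est_mu, est_sigma, 3, s0)
  })
  p_expected <- (1 + sum(abs(null_u) >= abs(u_obs))) / (1 + length(null_u))
  diffs <- data.frame(gene_id = "g1", d1 = d[1], d2 = d[2], d3 = d[3])
  p <- compute_pvalues(u_obs, diffs, method = "sign_permutation",
                       s0 = s0, delta = delta, config = cfg)
  expect_equal(p, p_expected)
  ## the two all-same-sign patterns are the only ones as extreme as observed
  expect_equal(p_expected, (1 + 2) / 9)
})

test_that("a zero statistic has p-value 1 under both methods", {
  d <- data.frame(gene_id = "g1", d1 = -1, d2 = 0, d3 = 1)
  p_perm <- compute_pvalues(0, d, method = "sign_permutation", s0 = 0.3,
                            delta = 0.2)
  p_t <- compute_pvalues(0, d, method = "t_reference")
  expect_equal(p_perm, 1)
  expect_equal(p_t, 1)
})

test_that("pooled permutation p-values are invariant under gene relabelling", {
  set.seed(33)
  d <- matrix(rnorm(15, 0.5, 0.3), 5, 3)
  diffs <- data.frame(gene_id = paste0("g", 1:5), d)
  u <- rowMeans(d) / (apply(d, 1, sd) / sqrt(3) + 0.1)
  p <- compute_pvalues(u, diffs, method = "sign_permutation", s0 = 0.1,
                       delta = 0.2)
  perm <- c(3, 1, 5, 2, 4)
  p_perm <- compute_pvalues(u[perm], diffs[perm, ], method = "sign_permutation",
                            s0 = 0.1, delta = 0.2)
  expect_equal(p_perm, p[perm])
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(34)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), bh_stepup(p))
  ## monotone in p order and never below raw p
  ord <- order(p)
  expect_true(all(diff(bh_adjust(p)[ord]) >= 0))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("hybrid ranking orders by average rank with documented tie-breaks", {
  sc <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       beta_fc = c(2.0, 0.5, 1.0),
                       beta_sam = c(10, 1, 5),
                       p_value = c(0.01, 0.01, 0.01))
  out <- hybrid_rank_select(sc)
  expect_equal(out$gene_id, c("g1", "g3", "g2"))
  expect_equal(out$avg_rank, (out$fc_rank + out$sam_rank) / 2)
  ## tied average ranks resolved by the smaller statistic rank
  sc2 <- tibble::tibble(gene_id = c("g1", "g2"),
                        beta_fc = c(2.0, 1.0),
                        beta_sam = c(1, 5),
                        p_value = c(0.01, 0.01))
  out2 <- hybrid_rank_select(sc2)
  expect_equal(out2$avg_rank, c(1.5, 1.5))
  expect_equal(out2$gene_id, c("g2", "g1"))
})

test_that("selection is a prefix that stops at the first failing p-value", {
  sc <- tibble::tibble(gene_id = paste0("g", 1:5),
                       beta_fc = c(5, 4, 3, 2, 1),
                       beta_sam = c(50, 40, 30, 20, 10),
                       p_value = c(0.01, 0.05, 0.2, 0.01, 0.01))
  out <- hybrid_rank_select(sc, p_cutoff = 0.1)
  expect_equal(out$selected, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  ## all p at or above the cutoff: empty selection
  sc$p_value <- rep(0.5, 5)
  expect_equal(sum(hybrid_rank_select(sc, p_cutoff = 0.1)$selected), 0)
  ## adjusted-p mode
  sc$p_value <- rep(0.001, 5)
  sc$p_adjusted <- c(0.01, 0.01, 0.2, 0.2, 0.2)
  out_adj <- hybrid_rank_select(sc, use_adjusted = TRUE, adj_cutoff = 0.05)
  expect_equal(sum(out_adj$selected), 2)
})

test_that("the ordering is invariant under monotone transforms of |beta-FC|", {
  set.seed(35)
  sc <- tibble::tibble(gene_id = paste0("g", 1:40),
                       beta_fc = rnorm(40),
                       beta_sam = rnorm(40),
                       p_value = runif(40))
  base <- hybrid_rank_select(sc)$gene_id
  sc2 <- sc
  sc2$beta_fc <- sign(sc$beta_fc) * (exp(abs(sc$beta_fc)) + 5)  # monotone in |fc|
  expect_equal(hybrid_rank_select(sc2)$gene_id, base)
})
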