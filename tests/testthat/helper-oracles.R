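## Independent oracles used across the suite. These deliberately avoid the
## package's computational paths: brute force, closed forms, enumeration.

## Dense grid search of the empirical beta-divergence objective. The scale
## grid is bounded below at a fraction of the robust dispersion: below that
## the objective diverges to -Inf on degenerate point-cluster collapses,
## which are not location/scale estimates of the sample.
grid_search_dpd <- function(d, beta, n_mu = 400, n_sd = 400,
                            mu_lim = range(d) + c(-1, 1) * diff(range(d)),
                            sd_lim = c(max(mad(d), 1e-6) / 4,
                                       2 * diff(range(d)))) {
  mus <- seq(mu_lim[1], mu_lim[2], length.out = n_mu)
  sds <- exp(seq(log(sd_lim[1]), log(sd_lim[2]), length.out = n_sd))
  best <- list(obj = Inf)
  for (s in sds) {
    w_bar <- rowMeans(exp(-beta * outer(mus, d, `-`)^2 / (2 * s^2)))
    obj <- log(2 * pi * s^2) / (2 * (1 + beta)) - log(w_bar) / beta
    i <- which.min(obj)
    if (obj[i] < best$obj) best <- list(obj = obj[i], mu = mus[i], sd = s)
  }
  best
}

## Step-up BH adjustment from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

## Two-pass mean / (n-1)-sd.
two_pass_mean_sd <- function(d) {
  mu <- sum(d) / length(d)
  list(mu = mu, sigma = sqrt(sum((d - mu)^2) / (length(d) - 1)))
}

## Mann-Whitney probability by brute-force pair counting (ties count 1/2).
pair_count_auc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## A tiny clean fixture: `n_de` strong DE genes among `n_genes`, near-zero
## noise so separation is unambiguous.
make_clean_fixture <- function(n_genes = 100, n_de = 5, n = 3, sigma = 1e-4,
                               effect = 2, seed = 42) {
  cfg <- simulation_config(n_genes = n_genes, prop_de = n_de / n_genes, n = n,
                           sigma = sigma, de_means = "fixed",
                           fixed_effect = effect, seed = seed)
  simulate_paired_expression(cfg)
}
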