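#' Estimation settings for the minimum beta-divergence fit
#'
#' Collects the tuning constants of the robust per-gene location/scale
#' estimation and outlier-calling stage.
#'
#' @param beta Divergence tuning parameter (> 0 downweights outliers; 0
#'   recovers maximum likelihood). Default 0.2.
#' @param alpha Interpolation fraction used by the adaptive weight cutoff
#'   `delta0 = min(w) + alpha * (max(w) - min(w))`. Default 0.1.
#' @param delta_cap Upper cap on the outlier cutoff, `delta = min(delta_cap,
#'   delta0)`. Default 0.2.
#' @param tol Convergence tolerance on the maximum absolute change of
#'   `(mu, sigma^2)` between fixed-point iterations.
#' @param max_iter Iteration cap.
#' @param scale_floor Genome-level stabilisation used by
#'   [compute_weight_matrix()]: each robust scale is floored at `scale_floor`
#'   times the genome median of the unfloored robust scales. The paired model
#'   assumes a common observation variance across genes, which is what makes a
#'   pooled floor meaningful; it prevents degenerate near-zero scales (the
#'   empirical beta-divergence objective is unbounded below as sigma -> 0 at
#'   small n) from turning ordinary replicates into spurious outliers. Set to
#'   0 to disable. Default 0.5.
#' @param delta_pool Which weights enter the `delta0` computation: `"all"`
#'   (every gene and replicate, the default) or `"per_gene_min"` (the per-gene
#'   smallest weights only).
#' @return A list of class `beta_config`.
#' @export
beta_config <- function(beta = 0.2, alpha = 0.1, delta_cap = 0.2,
                        tol = 1e-8, max_iter = 100L, scale_floor = 0.5,
                        delta_pool = c("all", "per_gene_min")) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(delta_cap), delta_cap > 0, delta_cap <= 1,
            is.numeric(tol), tol > 0,
            max_iter >= 1, scale_floor >= 0)
  structure(list(beta = beta, alpha = alpha, delta_cap = delta_cap,
                 tol = tol, max_iter = as.integer(max_iter),
                 scale_floor = scale_floor,
                 delta_pool = match.arg(delta_pool)),
            class = "beta_config")
}

new_ls_estimate <- function(mu, sigma, kind, weights, is_outlying_gene = FALSE,
                            converged = TRUE, iterations = 0L) {
  structure(list(mu = mu, sigma = sigma, kind = kind, weights = weights,
                 is_outlying_gene = is_outlying_gene, converged = converged,
                 iterations = as.integer(iterations)),
            class = "ls_estimate")
}

#' @export
print.ls_estimate <- function(x, ...) {
  cat(sprintf("<%s estimate>  mu = %.6g  sigma = %.6g%s\n", x$kind, x$mu,
              x$sigma,
              if (x$kind == "robust" && !x$converged) "  (not converged)" else ""))
  invisible(x)
}

#' Classical (maximum-likelihood) location/scale of paired differences
#'
#' The arithmetic mean and the (n-1)-divisor standard deviation of a gene's
#' paired-difference vector; these are the `r_g` and `s_g` that enter the
#' classical SAM statistic.
#'
#' @param d Numeric vector of paired differences (length >= 2).
#' @return An `ls_estimate` with `kind = "classical"` and unit weights.
#' @examples
#' mle_estimate(c(1, 2, 3))  # mu = 2, sigma = 1
#' @export
mle_estimate <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 2L) stop("need n >= 2 to estimate a scale", call. = FALSE)
  if (!all(is.finite(d))) stop("differences must be finite", call. = FALSE)
  mu <- mean(d)
  sigma <- sqrt(sum((d - mu)^2) / (length(d) - 1L))
  new_ls_estimate(mu, sigma, "classical", rep(1, length(d)))
}

#' Classical one-sample (paired) t statistic
#'
#' `t = mean(d) / (sd(d) / sqrt(n))`, referred to a Student-t distribution
#' with n - 1 degrees of freedom. A zero sample standard deviation returns a
#' signed infinity (ordering-wise the most extreme value) with a warning; the
#' SAM-type statistics avoid this case through the fudge factor s0.
#'
#' @inheritParams mle_estimate
#' @return A scalar t statistic.
#' @examples
#' paired_t_statistic(c(1, 2, 3))  # ~ 3.4641
#' @export
paired_t_statistic <- function(d) {
  est <- mle_estimate(d)
  n <- length(d)
  if (est$sigma == 0) {
    warning("zero variance difference vector; returning signed infinity",
            call. = FALSE)
    return(sign(est$mu) * Inf)
  }
  est$mu / (est$sigma / sqrt(n))
}

#' The beta-weight function
#'
#' `exp(-beta * (d - mu)^2 / (2 * sigma^2))`: 1 for an observation at the
#' centre (or when beta = 0), decaying towards 0 as the residual grows. It is
#' both the estimating weight of the minimum beta-divergence fixed point and
#' the outlier score compared against the adaptive cutoff delta.
#'
#' @param d Observation(s); vectorised.
#' @param mu Location.
#' @param sigma Scale (> 0).
#' @param beta Tuning parameter (>= 0).
#' @return Weight(s) in (0, 1].
#' @examples
#' beta_weight(0, 0, 1, 0.2)       # 1
#' beta_weight(3, 0, 1, 0.2)       # downweighted
#' @export
beta_weight <- function(d, mu, sigma, beta) {
  stopifnot(beta >= 0)
  if (any(sigma <= 0)) stop("beta_weight undefined for sigma <= 0", call. = FALSE)
  exp(-beta * (d - mu)^2 / (2 * sigma^2))
}

#' Empirical beta-divergence objective for a Gaussian model
#'
#' The empirical cross-entropy criterion minimised by the robust estimator,
#' `log(2*pi*sigma2) / (2*(1+beta)) - log(mean(w)) / beta` with `w` the
#' beta-weights of `d` under `(mu, sigma2)`. Setting its `(mu, sigma2)`
#' gradient to zero yields exactly the fixed-point updates (weighted mean;
#' `(1+beta)` times the weighted mean squared deviation), so independent grid
#' search over this function is a direct oracle for the iterative fit. As
#' `beta -> 0` it converges to the Gaussian negative log-likelihood per
#' observation.
#'
#' @inheritParams mle_estimate
#' @param mu,sigma2 Candidate location and variance.
#' @param beta Tuning parameter (> 0).
#' @return Scalar objective value (smaller is better).
#' @export
beta_divergence_objective <- function(d, mu, sigma2, beta) {
  stopifnot(beta > 0, sigma2 > 0)
  w_bar <- mean(exp(-beta * (d - mu)^2 / (2 * sigma2)))
  if (w_bar == 0) return(Inf)
  log(2 * pi * sigma2) / (2 * (1 + beta)) - log(w_bar) / beta
}

## Row-wise objective for a matrix of difference vectors.
dpd_objective_rows <- function(d, mu, s2, beta) {
  w_bar <- rowMeans(exp(-beta * (d - mu)^2 / (2 * s2)))
  ifelse(w_bar == 0, Inf,
         log(2 * pi * s2) / (2 * (1 + beta)) - log(w_bar) / beta)
}

## One fixed-point run for all rows of d from the given start.
## mu, s2 are vectors (one per row). Returns mu, s2, iterations, converged.
dpd_iterate_rows <- function(d, mu, s2, beta, tol, max_iter) {
  G <- nrow(d)
  conv <- rep(FALSE, G)
  iters <- max_iter
  for (it in seq_len(max_iter)) {
    w <- exp(-beta * (d - mu)^2 / (2 * s2))
    sw <- rowSums(w)
    mu_new <- rowSums(w * d) / sw
    s2_new <- pmax((beta + 1) * rowSums(w * (d - mu)^2) / sw, 1e-300)
    delta <- pmax(abs(mu_new - mu), abs(s2_new - s2))
    mu <- mu_new
    s2 <- s2_new
    if (max(delta) < tol) {
      conv <- rep(TRUE, G)
      iters <- it
      break
    }
  }
  if (!all(conv)) conv <- rep(FALSE, G)
  list(mu = mu, s2 = s2, iterations = iters, converged = conv[1])
}

## Multi-start robust fit for all rows: MLE start and median/MAD start, keep
## the solution with the lower empirical beta-divergence objective per row.
## With `pooled_floor = TRUE` (the genome-wide path) both candidate scales are
## first floored at config$scale_floor times the genome median of the smaller
## candidate scale; the floored objectives then decide, so a degenerate
## near-zero-scale solution is penalised for the residual it hides rather
## than rewarded for its collapsing density.
fit_robust_rows <- function(d, config, pooled_floor = FALSE) {
  beta <- config$beta
  n <- ncol(d)
  mu0 <- rowMeans(d)
  s2_mle <- pmax(rowSums((d - mu0)^2) / n, 1e-300)
  if (beta == 0) {
    ## weights are identically 1: the fixed point is the divisor-n MLE
    return(list(mu = mu0, s2 = s2_mle, iterations = 1L,
                converged = rep(TRUE, nrow(d))))
  }
  a <- dpd_iterate_rows(d, mu0, s2_mle, beta, config$tol, config$max_iter)
  med <- apply(d, 1, median)
  s2_mad <- pmax(apply(d, 1, mad)^2, 1e-300)
  ## degenerate MAD (e.g. duplicated values) falls back to the MLE scale
  s2_mad <- ifelse(s2_mad <= 1e-290, s2_mle, s2_mad)
  b <- dpd_iterate_rows(d, med, s2_mad, beta, config$tol, config$max_iter)
  if (pooled_floor && config$scale_floor > 0) {
    constant <- s2_mle <= 1e-290
    s2_small <- pmin(a$s2, b$s2)
    if (any(!constant)) {
      floor2 <- (config$scale_floor * median(sqrt(s2_small[!constant])))^2
      a$s2 <- pmax(a$s2, floor2)
      b$s2 <- pmax(b$s2, floor2)
    }
  }
  oa <- dpd_objective_rows(d, a$mu, a$s2, beta)
  ob <- dpd_objective_rows(d, b$mu, b$s2, beta)
  use_b <- is.finite(ob) & (!is.finite(oa) | ob < oa)
  list(mu = ifelse(use_b, b$mu, a$mu),
       s2 = ifelse(use_b, b$s2, a$s2),
       iterations = max(a$iterations, b$iterations),
       converged = rep(a$converged && b$converged, nrow(d)))
}

#' Minimum beta-divergence location/scale estimate for one gene
#'
#' Robust M-estimation of `(mu, sigma^2)` for a paired-difference vector by
#' the fixed-point iteration `mu <- weighted mean`, `sigma^2 <- (beta + 1) *
#' weighted mean squared deviation`, with beta-weights recomputed each pass.
#' The iteration is run from two starts -- the maximum-likelihood estimate and
#' a median/MAD estimate -- and the iterate with the smaller empirical
#' beta-divergence objective is returned, since the objective is multimodal
#' in the presence of outliers and the MLE start can be trapped in a
#' non-robust local minimum.
#'
#' With `beta = 0` all weights are 1 and the estimate is exactly the
#' divisor-n maximum-likelihood fit.
#'
#' @inheritParams mle_estimate
#' @param config A [beta_config()].
#' @return An `ls_estimate` with `kind = "robust"`, the final beta-weights,
#'   and convergence information.
#' @examples
#' minimum_beta_divergence_estimate(c(0.9, 1.0, 1.1, 20))$mu  # ~ 1, not ~ 5.75
#' @export
minimum_beta_divergence_estimate <- function(d, config = beta_config()) {
  d <- as.numeric(d)
  if (length(d) < 2L) stop("need n >= 2", call. = FALSE)
  if (!all(is.finite(d))) stop("differences must be finite", call. = FALSE)
  if (diff(range(d)) == 0) {
    stop("all differences equal; robust scale is degenerate", call. = FALSE)
  }
  dm <- matrix(d, nrow = 1L)
  fit <- fit_robust_rows(dm, config)
  if (!fit$converged[1]) {
    warning("fixed-point iteration did not converge within max_iter; ",
            "returning best iterate", call. = FALSE)
  }
  sigma <- sqrt(fit$s2[1])
  w <- if (config$beta == 0) rep(1, length(d)) else {
    beta_weight(d, fit$mu[1], sigma, config$beta)
  }
  new_ls_estimate(fit$mu[1], sigma, "robust", w,
                  converged = fit$converged[1], iterations = fit$iterations)
}
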