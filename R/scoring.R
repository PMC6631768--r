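#' Select the SAM fudge factor s0
#'
#' Evaluates candidate values of s0 at the 0, 5, ..., 100 percentiles of the
#' scaled standard deviations `s* = s / sqrt(n)` and keeps the candidate that
#' minimises the coefficient of variation of the moderated statistic
#' `u = r / (s* + s0)`.
#'
#' Two notions of the coefficient of variation are offered. The default,
#' `"mad_window"`, is the SAM recipe: genes are sliced into quantile windows
#' of `s*`, the median absolute deviation of `u` is computed per window, and
#' the CV of those window MADs is minimised -- this measures how much the
#' spread of the statistic depends on the variance level, which is what s0 is
#' meant to flatten. `"simple"` is the genome-wide `sd(u) / |mean(u)|`; with
#' both up- and down-regulated genes `mean(u)` sits near zero, which makes
#' this ratio numerically erratic, so it is provided for completeness rather
#' than as the default.
#'
#' @param scaled_sds Vector of per-gene scaled standard deviations `s*`.
#' @param means Vector of per-gene mean differences `r`.
#' @param method `"mad_window"` (default) or `"simple"`.
#' @param probs Candidate percentile levels. Default `seq(0, 1, 0.05)`.
#' @param n_windows Number of quantile windows for `"mad_window"`; reduced
#'   automatically for small genomes.
#' @return A list of class `s0_selection`: `s0`, `candidate_grid` (tibble of
#'   percentile level and value) and `cv_values`. Ties are broken to the
#'   smallest candidate.
#' @export
select_s0 <- function(scaled_sds, means, method = c("mad_window", "simple"),
                      probs = seq(0, 1, by = 0.05), n_windows = 100L) {
  method <- match.arg(method)
  s <- as.numeric(scaled_sds)
  r <- as.numeric(means)
  stopifnot(length(s) == length(r))
  if (sum(s > 0) < 2L) stop("need at least 2 genes with positive scale", call. = FALSE)
  cands <- unname(quantile(s, probs, type = 7))
  nwin <- max(2L, min(as.integer(n_windows), floor(length(s) / 2L)))
  grp <- cut(rank(s, ties.method = "first"), nwin, labels = FALSE)
  cv_one <- function(s0) {
    u <- r / (s + s0)
    if (method == "simple") {
      sdu <- sd(u)
      if (sdu == 0) return(0)
      return(sdu / abs(mean(u)))
    }
    v <- tapply(u, grp, mad)
    mv <- mean(v)
    if (sd(v) == 0 && mv == 0) return(0)
    sd(v) / mv
  }
  cv <- vapply(cands, cv_one, numeric(1))
  ok <- is.finite(cv)
  idx <- if (any(ok)) which(cv == min(cv[ok]))[1] else 1L
  structure(list(s0 = cands[idx],
                 candidate_grid = tibble(prob = probs, value = cands),
                 cv_values = cv, method = method),
            class = "s0_selection")
}

#' @export
print.s0_selection <- function(x, ...) {
  cat(sprintf("s0 = %.6g (%s CV criterion over %d percentile candidates)\n",
              x$s0, x$method, length(x$cv_values)))
  invisible(x)
}

#' The (beta-)SAM statistic
#'
#' `u = mu / (sigma / sqrt(n) + s0)`. With the unified robust/classical
#' estimates this is the beta-SAM statistic; with classical estimates (or
#' beta = 0) it is the ordinary SAM statistic.
#'
#' @param mu Location estimate(s); vectorised.
#' @param sigma Scale estimate(s) (>= 0).
#' @param n Number of replicate pairs.
#' @param s0 Fudge factor (>= 0).
#' @return The statistic value(s).
#' @examples
#' beta_sam_statistic(2, 1, 4, 0)    # 4
#' beta_sam_statistic(2, 1, 4, 0.5)  # 2
#' @export
beta_sam_statistic <- function(mu, sigma, n, s0) {
  stopifnot(s0 >= 0, all(sigma >= 0), n >= 1)
  denom <- sigma / sqrt(n) + s0
  if (any(denom == 0)) {
    stop("zero denominator: sigma = 0 with s0 = 0", call. = FALSE)
  }
  mu / denom
}

#' The beta-FC (robust fold change)
#'
#' The robust location estimate for genes flagged as outlying, the classical
#' mean difference otherwise. With beta = 0 no gene is flagged and this is
#' the plain mean difference (the classical log fold change).
#'
#' @param classical Classical location(s): an `ls_estimate` or numeric vector.
#' @param robust Robust location(s): an `ls_estimate` or numeric vector.
#' @param is_outlying_gene Logical flag(s).
#' @return Fold-change value(s) on the scale of the input differences.
#' @export
beta_fc <- function(classical, robust, is_outlying_gene) {
  mu_c <- if (inherits(classical, "ls_estimate")) classical$mu else as.numeric(classical)
  mu_r <- if (inherits(robust, "ls_estimate")) robust$mu else as.numeric(robust)
  ifelse(is_outlying_gene, mu_r, mu_c)
}

## All 2^n sign patterns as an n x 2^n matrix of +/-1.
sign_patterns <- function(n) {
  stopifnot(n <= 20)
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t(unname(m))
}

#' P-values for the beta-SAM statistic
#'
#' `"sign_permutation"` (the default) generates the null by flipping the
#' signs of each gene's paired differences -- exhaustively over all `2^n`
#' patterns when `2^n <= 4096`, otherwise over `n_perm` seeded random
#' patterns -- recomputing the full unified beta-SAM statistic with the same
#' fixed s0 and cutoff delta, and pooling the null statistics across genes
#' and flips. The two-sided p-value of gene g is the add-one-smoothed
#' proportion of pooled null values at least as extreme as the observed one.
#' `"t_reference"` is a fast parametric fallback: a two-sided Student-t tail
#' with n - 1 degrees of freedom applied to `mu / (sigma / sqrt(n))`,
#' ignoring s0.
#'
#' @param statistics Observed beta-SAM statistics (one per gene).
#' @param diffs Differences as produced by [compute_differences()].
#' @param method `"sign_permutation"` or `"t_reference"`.
#' @param n_perm Number of random sign patterns when exhaustive enumeration
#'   is infeasible.
#' @param seed Integer seed controlling the random patterns.
#' @param s0 The fudge factor used for the observed statistics.
#' @param delta The outlier cutoff used for the observed statistics.
#' @param config The [beta_config()] used for the observed statistics.
#' @return Vector of p-values in `[0, 1]`.
#' @export
compute_pvalues <- function(statistics, diffs,
                            method = c("sign_permutation", "t_reference"),
                            n_perm = 100L, seed = 1L, s0 = 0,
                            delta = 0.2, config = beta_config()) {
  method <- match.arg(method)
  dm <- diffs_to_matrix(diffs)
  d <- dm$d
  n <- ncol(d)
  stopifnot(length(statistics) == nrow(d), all(is.finite(statistics)))
  if (method == "t_reference") {
    est <- genome_estimates(d, config)
    tt <- ifelse(est$sigma_unified == 0,
                 sign(est$mu_unified) * Inf,
                 est$mu_unified / (est$sigma_unified / sqrt(n)))
    return(2 * pt(-abs(tt), df = n - 1L))
  }
  exhaustive <- 2^n <= 4096
  patterns <- if (exhaustive) {
    sign_patterns(n)
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
    set.seed(seed)
    matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  }
  abs_obs <- abs(statistics)
  n_ge <- numeric(length(statistics))
  total <- 0L
  for (j in seq_len(ncol(patterns))) {
    dj <- sweep(d, 2, patterns[, j], `*`)
    est <- suppressWarnings(genome_estimates(dj, config, delta = delta))
    null_u <- beta_sam_statistic(est$mu_unified, est$sigma_unified, n, s0)
    abs_null <- abs(null_u)
    ord <- sort(abs_null)
    ## count pooled null values >= each observed |u|
    n_ge <- n_ge + (length(ord) - findInterval(abs_obs, ord, left.open = TRUE))
    total <- total + length(ord)
  }
  (1 + n_ge) / (1 + total)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] kept for a stable pipeline surface).
#'
#' @param p_values Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Hybrid fold-change / statistic rank selection of top genes
#'
#' Ranks `|beta-FC|` and `|beta-SAM|` separately in descending order
#' (fractional ranks for ties), averages the two ranks per gene, orders genes
#' by ascending average rank (ties broken by the smaller statistic rank, then
#' by gene identifier), and selects the leading run of that ordering while
#' the gene's p-value stays below the cutoff, stopping at the first failure
#' so the selection is always a prefix.
#'
#' @param scores A tibble with columns `gene_id`, `beta_fc`, `beta_sam`,
#'   `p_value` and (if `use_adjusted`) `p_adjusted`.
#' @param p_cutoff Raw p-value threshold for the stopping rule. Default 0.1.
#' @param use_adjusted Select on BH-adjusted p-values instead (threshold
#'   `adj_cutoff`); the default uses raw p-values.
#' @param adj_cutoff Adjusted p-value threshold when `use_adjusted = TRUE`.
#' @return The input tibble, reordered, with `fc_rank`, `sam_rank`,
#'   `avg_rank` and logical `selected` columns added.
#' @export
hybrid_rank_select <- function(scores, p_cutoff = 0.1, use_adjusted = FALSE,
                               adj_cutoff = 0.05) {
  stopifnot(all(c("gene_id", "beta_fc", "beta_sam", "p_value") %in% names(scores)))
  scores <- as_tibble(scores)
  scores$fc_rank <- rank(-abs(scores$beta_fc), ties.method = "average")
  scores$sam_rank <- rank(-abs(scores$beta_sam), ties.method = "average")
  scores$avg_rank <- (scores$fc_rank + scores$sam_rank) / 2
  ord <- order(scores$avg_rank, scores$sam_rank, scores$gene_id)
  scores <- scores[ord, , drop = FALSE]
  pv <- if (use_adjusted) {
    stopifnot("p_adjusted" %in% names(scores))
    scores$p_adjusted
  } else {
    scores$p_value
  }
  cut <- if (use_adjusted) adj_cutoff else p_cutoff
  pass <- pv < cut
  n_sel <- if (all(pass)) length(pass) else which(!pass)[1] - 1L
  scores$selected <- seq_along(pass) <= n_sel
  scores
}
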