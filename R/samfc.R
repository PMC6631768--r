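## Shared genome-wide estimation engine: classical and robust fits, weights,
## cutoff, and the unified per-gene (mu, sigma). `delta` can be fixed (for
## permutation nulls) or derived from the weight pool.
genome_estimates <- function(d, config, delta = NULL) {
  n <- ncol(d)
  mu0 <- rowMeans(d)
  sd0 <- sqrt(rowSums((d - mu0)^2) / (n - 1L))
  wm <- compute_weight_matrix(d, config)
  if (!is.null(delta)) {
    out <- apply(wm$weights, 1, min) <= delta
    constant <- apply(d, 1, function(r) diff(range(r)) == 0)
    out[constant] <- FALSE
    wm$delta <- delta
    wm$is_outlying_gene <- out
  }
  list(mu0 = mu0, sd0 = sd0,
       mu_rob = wm$mu, sigma_rob = wm$sigma,
       weights = wm$weights, smallest = wm$smallest_per_gene,
       delta = wm$delta, is_outlying_gene = wm$is_outlying_gene,
       mu_unified = ifelse(wm$is_outlying_gene, wm$mu, mu0),
       sigma_unified = ifelse(wm$is_outlying_gene, wm$sigma, sd0))
}

#' Hybrid robust SAM-FC differential expression for paired samples
#'
#' Runs the full pipeline on a paired two-condition expression table:
#' per-gene paired differences; classical and minimum beta-divergence
#' location/scale estimates; beta-weight outlier detection with the adaptive
#' cutoff delta; unification (robust estimates for contaminated genes,
#' maximum-likelihood for clean ones); fudge-factor s0 selection; the
#' beta-SAM statistic and beta-FC; p-values with Benjamini-Hochberg
#' adjustment; and the hybrid average-rank ordering with prefix selection of
#' top genes.
#'
#' @inheritParams paired_experiment
#' @param beta,alpha,delta_cap,scale_floor Estimation constants; see
#'   [beta_config()].
#' @param s0_method Fudge-factor criterion, see [select_s0()].
#' @param pvalue_method `"sign_permutation"` (default) or `"t_reference"`;
#'   see [compute_pvalues()].
#' @param n_perm Random sign patterns when exhaustive flipping is infeasible.
#' @param p_cutoff Raw p-value threshold of the selection stopping rule.
#' @param use_adjusted Select on BH-adjusted p-values (threshold
#'   `adj_cutoff`) instead of raw ones.
#' @param adj_cutoff Adjusted-p threshold when `use_adjusted = TRUE`.
#' @param seed Integer seed for the permutation null.
#' @param config Optionally a full [beta_config()]; overrides the individual
#'   constants.
#' @return An object of class `samfc_fit` with elements `scores` (a tibble:
#'   `gene_id`, `beta_fc`, `beta_sam`, `p_value`, `p_adjusted`, `fc_rank`,
#'   `sam_rank`, `avg_rank`, `is_outlying_gene`, `smallest_weight`,
#'   `selected`, ordered by average rank), `delta`, `s0`, `weights`, and
#'   `params`. [tidy()] returns the score table, [glance()] a one-row run
#'   summary, and [autoplot()] the smallest-weight diagnostic plot.
#' @examples
#' sim <- simulate_paired_expression(simulation_config(n_genes = 200, n = 3,
#'                                                     seed = 7))
#' fit <- samfc(sim$data, seed = 7)
#' head(tidy(fit))
#' glance(fit)
#' @export
samfc <- function(data, pairs = NULL, gene_col = 1L,
                  beta = 0.2, alpha = 0.1, delta_cap = 0.2, scale_floor = 0.5,
                  s0_method = c("mad_window", "simple"),
                  pvalue_method = c("sign_permutation", "t_reference"),
                  n_perm = 100L, p_cutoff = 0.1, use_adjusted = FALSE,
                  adj_cutoff = 0.05, seed = 1L, config = NULL) {
  s0_method <- match.arg(s0_method)
  pvalue_method <- match.arg(pvalue_method)
  if (is.null(config)) {
    config <- beta_config(beta = beta, alpha = alpha, delta_cap = delta_cap,
                          scale_floor = scale_floor)
  }
  pe <- as_paired_exp(data, pairs, gene_col)
  d <- diff_matrix(pe)
  n <- pe$n
  est <- genome_estimates(d, config)
  s_star <- est$sigma_unified / sqrt(n)
  s0_sel <- select_s0(s_star, est$mu_unified, method = s0_method)
  s0 <- s0_sel$s0
  u <- beta_sam_statistic(est$mu_unified, est$sigma_unified, n, s0)
  fc <- beta_fc(est$mu0, est$mu_rob, est$is_outlying_gene)
  diffs_tbl <- cbind(data.frame(gene_id = pe$gene_ids),
                     as.data.frame(d))
  pv <- compute_pvalues(u, diffs_tbl, method = pvalue_method,
                        n_perm = n_perm, seed = seed, s0 = s0,
                        delta = est$delta, config = config)
  scores <- tibble(
    gene_id = pe$gene_ids,
    beta_fc = fc,
    beta_sam = u,
    p_value = pv,
    p_adjusted = bh_adjust(pv),
    is_outlying_gene = est$is_outlying_gene,
    smallest_weight = est$smallest
  )
  scores <- hybrid_rank_select(scores, p_cutoff = p_cutoff,
                               use_adjusted = use_adjusted,
                               adj_cutoff = adj_cutoff)
  structure(
    list(scores = scores, delta = est$delta, s0 = s0, s0_selection = s0_sel,
         weights = est$weights,
         params = list(beta = config$beta, alpha = config$alpha,
                       delta_cap = config$delta_cap,
                       scale_floor = config$scale_floor,
                       s0_method = s0_method, pvalue_method = pvalue_method,
                       n_perm = n_perm, p_cutoff = p_cutoff,
                       use_adjusted = use_adjusted, adj_cutoff = adj_cutoff,
                       seed = seed, n = n, n_genes = length(pe$gene_ids))),
    class = "samfc_fit"
  )
}

#' @export
print.samfc_fit <- function(x, ...) {
  p <- x$params
  cat("Hybrid robust SAM-FC fit\n")
  cat(sprintf("  genes: %d   pairs (n): %d   beta = %g\n",
              p$n_genes, p$n, p$beta))
  cat(sprintf("  delta = %.4g   s0 = %.4g (%s)\n", x$delta, x$s0, p$s0_method))
  cat(sprintf("  outlying genes: %d (%.1f%%)\n",
              sum(x$scores$is_outlying_gene),
              100 * mean(x$scores$is_outlying_gene)))
  cat(sprintf("  selected top genes: %d (%s)\n", sum(x$scores$selected),
              if (p$use_adjusted) sprintf("adjusted p < %g", p$adj_cutoff)
              else sprintf("p < %g", p$p_cutoff)))
  invisible(x)
}

#' @rdname samfc
#' @param x A `samfc_fit`.
#' @param ... Unused.
#' @method tidy samfc_fit
#' @export
tidy.samfc_fit <- function(x, ...) {
  x$scores
}

#' @rdname samfc
#' @method glance samfc_fit
#' @export
glance.samfc_fit <- function(x, ...) {
  p <- x$params
  tibble(n_genes = p$n_genes, n = p$n, beta = p$beta, delta = x$delta,
         s0 = x$s0, n_outlying = sum(x$scores$is_outlying_gene),
         n_selected = sum(x$scores$selected))
}

#' Diagnostic plot of per-gene smallest beta-weights
#'
#' Scatter of the smallest beta-weight of each gene against gene index with
#' the adaptive cutoff delta as a horizontal line; genes at or below the line
#' are the outlier-contaminated ones whose estimates are replaced by the
#' robust fit.
#'
#' @param object A `samfc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot samfc_fit
#' @export
autoplot.samfc_fit <- function(object, ...) {
  smallest <- apply(object$weights, 1, min)
  df <- tibble(
    index = seq_along(smallest),
    smallest_weight = smallest,
    outlying = factor(ifelse(smallest <= object$delta, "outlying", "usual"),
                      levels = c("usual", "outlying"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$smallest_weight,
                                   colour = .data$outlying)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$delta, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(usual = "black", outlying = "red")) +
    ggplot2::labs(x = "gene index", y = "smallest beta-weight",
                  colour = NULL,
                  title = sprintf("Smallest beta-weights (delta = %.3g)",
                                  object$delta)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a fit
#'
#' Minus log10 p-value against beta-FC, with selected genes highlighted.
#'
#' @param fit A `samfc_fit`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(fit) {
  stopifnot(inherits(fit, "samfc_fit"))
  df <- fit$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "beta-FC (log-scale mean difference)",
                  y = "-log10 p", colour = "selected") +
    ggplot2::theme_minimal()
}
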