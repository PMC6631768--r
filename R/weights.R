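#' Adaptive cutoff for beta-weights
#'
#' `delta0 = min(pool) + alpha * (max(pool) - min(pool))`, capped at
#' `delta_cap`: `delta = min(delta_cap, delta0)`. A replicate whose
#' beta-weight falls at or below `delta` is called an outlying expression.
#'
#' @param pool Numeric vector of beta-weights (all genes and replicates by
#'   default in the genome-wide pipeline).
#' @param config A [beta_config()] supplying `alpha` and `delta_cap`.
#' @return The scalar cutoff `delta`.
#' @examples
#' delta_cutoff(c(0.05, 0.5, 0.95))  # 0.05 + 0.1 * 0.9 = 0.14
#' delta_cutoff(rep(0.9, 10))        # capped at 0.2
#' @export
delta_cutoff <- function(pool, config = beta_config()) {
  pool <- as.numeric(pool)
  if (length(pool) == 0) stop("empty weight pool", call. = FALSE)
  if (any(pool < 0 | pool > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  delta0 <- min(pool) + config$alpha * (max(pool) - min(pool))
  min(config$delta_cap, delta0)
}

#' Outlier call for one gene from its beta-weights
#'
#' A gene is outlying when at least one replicate weight is at or below the
#' cutoff (the boundary counts as an outlier).
#'
#' @param weights_row Numeric vector of the gene's beta-weights.
#' @param delta Scalar cutoff from [delta_cutoff()].
#' @return Logical: does the gene contain at least one outlying expression?
#' @examples
#' classify_gene(c(0.8, 0.1, 0.9), 0.2)  # TRUE
#' classify_gene(c(0.8, 0.9, 0.7), 0.2)  # FALSE
#' @export
classify_gene <- function(weights_row, delta) {
  any(weights_row <= delta)
}

#' Genome-wide beta-weight matrix, cutoff and outlier flags
#'
#' Fits the robust location/scale for every gene, evaluates the beta-weight
#' of every replicate under its gene's robust fit, and derives the adaptive
#' cutoff `delta` from the pooled weights. When `config$scale_floor > 0` the
#' per-gene robust scales are floored at `scale_floor` times the genome
#' median of the unfloored robust scales before weights are computed (see
#' [beta_config()]); genes with a degenerate (zero) scale are excluded from
#' the cutoff pool, given unit weights, and treated as non-outlying.
#'
#' @param diffs Differences as produced by [compute_differences()] (or a
#'   numeric matrix of per-gene difference vectors).
#' @param config A [beta_config()].
#' @param robust Optional precomputed robust fit (list with `mu`, `s2`) to
#'   reuse; mainly internal.
#' @return A list of class `weight_matrix`: `weights` (genes x n),
#'   `smallest_per_gene`, `delta`, `is_outlying_gene`, and the (floored)
#'   robust `mu` and `sigma` used to evaluate the weights.
#' @export
compute_weight_matrix <- function(diffs, config = beta_config(), robust = NULL) {
  dm <- diffs_to_matrix(diffs)
  d <- dm$d
  if (is.null(robust)) robust <- fit_robust_rows(d, config, pooled_floor = TRUE)
  constant <- apply(d, 1, function(r) diff(range(r)) == 0)
  s2 <- robust$s2
  sigma <- sqrt(s2)
  w <- if (config$beta == 0) {
    matrix(1, nrow(d), ncol(d))
  } else {
    exp(-config$beta * (d - robust$mu)^2 / (2 * s2))
  }
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) excluded from the cutoff pool ",
            "and treated as non-outlying", call. = FALSE)
    w[constant, ] <- 1
  }
  pool <- if (config$delta_pool == "per_gene_min") {
    apply(w[!constant, , drop = FALSE], 1, min)
  } else {
    as.vector(w[!constant, , drop = FALSE])
  }
  ## an all-constant genome has no informative weights; the cap is the only
  ## sensible cutoff and nothing can be flagged anyway
  delta <- if (length(pool) == 0) config$delta_cap else delta_cutoff(pool, config)
  smallest <- apply(w, 1, min)
  out <- smallest <= delta
  out[constant] <- FALSE
  structure(list(weights = w, smallest_per_gene = smallest, delta = delta,
                 is_outlying_gene = out, mu = robust$mu, sigma = sigma,
                 gene_id = dm$gene_id),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("beta-weight matrix: %d genes x %d replicates, delta = %.4g, %d outlying gene(s)\n",
              nrow(x$weights), ncol(x$weights), x$delta, sum(x$is_outlying_gene)))
  invisible(x)
}

#' Unify classical and robust estimates for one gene
#'
#' Returns the robust estimate when the gene contains at least one outlying
#' expression and the classical (maximum-likelihood) estimate otherwise, so
#' that the efficient estimator is used on clean genes and the robust one
#' only where contamination was detected.
#'
#' @param classical,robust `ls_estimate` objects for the same gene.
#' @param is_outlying_gene Logical outlier call from [classify_gene()].
#' @return The chosen `ls_estimate`, with `is_outlying_gene` recorded.
#' @export
unify_estimates <- function(classical, robust, is_outlying_gene) {
  stopifnot(inherits(classical, "ls_estimate"), inherits(robust, "ls_estimate"))
  chosen <- if (is_outlying_gene) robust else classical
  chosen$is_outlying_gene <- is_outlying_gene
  chosen
}
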