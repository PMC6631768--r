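#' Configuration for the synthetic paired-expression generator
#'
#' Describes a two-condition paired Gaussian genome: every gene's expression
#' is `N(mu_gi, sigma^2)`; equally expressed genes share one mean drawn from
#' `mu_range`, differentially expressed genes draw the two condition means
#' independently from `mu_range` (yielding a spectrum of effect sizes), and
#' an optional contamination step plants one-sided outlying expressions via
#' `x* = d + 2 * max(condition values)` with `d` drawn from `d_range`.
#'
#' @param n_genes Number of genes. Default 10000.
#' @param prop_de Proportion of differentially expressed genes. Default 0.03.
#' @param n Replicate pairs per condition. Default 3.
#' @param mu_range Interval the per-condition means are drawn from.
#'   Default `c(3, 5)`.
#' @param sigma Per-observation standard deviation. Default 0.05 (the noise
#'   scale consistent with the benchmark operating characteristics this
#'   generator is designed to emulate; see the methods vignette).
#' @param de_means `"independent"` (default): each DE gene draws its two
#'   condition means independently from `mu_range` (redrawn in the
#'   measure-zero event of equality); `"fixed"`: condition means differ by
#'   exactly `fixed_effect` with a random sign.
#' @param fixed_effect Mean shift used when `de_means = "fixed"`. Default 2.
#' @param contamination `"none"` (default), `"per_gene_fraction"` (a random
#'   `outlier_genes_fraction` of genes receive outliers) or `"all_genes"`.
#' @param outlier_genes_fraction Fraction of genes contaminated under
#'   `"per_gene_fraction"`. Default 0.05.
#' @param outliers_per_gene `1`, `2`, or `"one_or_two"` (drawn uniformly per
#'   gene). Default 1.
#' @param d_range Interval for the outlier shift `d`. Default `c(5, 10)`.
#' @param fixed_d Optional fixed outlier shift overriding `d_range`.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000L, prop_de = 0.03, n = 3L,
                              mu_range = c(3, 5), sigma = 0.05,
                              de_means = c("independent", "fixed"),
                              fixed_effect = 2,
                              contamination = c("none", "per_gene_fraction",
                                                "all_genes"),
                              outlier_genes_fraction = 0.05,
                              outliers_per_gene = 1L,
                              d_range = c(5, 10), fixed_d = NULL,
                              seed = 1L) {
  de_means <- match.arg(de_means)
  contamination <- match.arg(contamination)
  stopifnot(n_genes >= 2, prop_de > 0, prop_de < 1, n >= 2,
            length(mu_range) == 2L, mu_range[1] < mu_range[2],
            sigma > 0, fixed_effect > 0,
            outlier_genes_fraction > 0, outlier_genes_fraction <= 1,
            length(d_range) == 2L, d_range[1] <= d_range[2], d_range[1] > 0)
  if (!(identical(outliers_per_gene, "one_or_two") ||
        (is.numeric(outliers_per_gene) && outliers_per_gene %in% c(1, 2)))) {
    stop("`outliers_per_gene` must be 1, 2 or \"one_or_two\"", call. = FALSE)
  }
  if (!is.null(fixed_d)) stopifnot(fixed_d > 0)
  structure(list(n_genes = as.integer(n_genes), prop_de = prop_de,
                 n = as.integer(n), mu_range = mu_range, sigma = sigma,
                 de_means = de_means, fixed_effect = fixed_effect,
                 contamination = contamination,
                 outlier_genes_fraction = outlier_genes_fraction,
                 outliers_per_gene = outliers_per_gene,
                 d_range = d_range, fixed_d = fixed_d,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic paired two-condition expression dataset
#'
#' Draws the genome described by a [simulation_config()]: DE genes are a
#' seeded random subset of exactly `round(prop_de * n_genes)` genes; every
#' expression value is Gaussian with the gene/condition mean and common
#' standard deviation `sigma`. If the config requests contamination the
#' dataset is passed through [contaminate_dataset()] before being returned.
#'
#' @param config A [simulation_config()].
#' @return A list of class `samfc_sim`: `data` (tibble: `gene_id`, condition-1
#'   columns `c1_1..c1_n`, condition-2 columns `c2_1..c2_n`), `is_de`
#'   (logical), `outlier_mask` (genes x 2n logical), `mu1`, `mu2`,
#'   `original_values` (pre-contamination values at masked entries), and
#'   `config`.
#' @examples
#' sim <- simulate_paired_expression(simulation_config(n_genes = 100, seed = 3))
#' sum(sim$is_de)  # 3
#' @export
simulate_paired_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$n_genes
  n <- config$n
  n_de <- round(config$prop_de * G)
  is_de <- logical(G)
  is_de[sample.int(G, n_de)] <- TRUE
  mu1 <- runif(G, config$mu_range[1], config$mu_range[2])
  mu2 <- mu1
  if (config$de_means == "independent") {
    m2 <- runif(n_de, config$mu_range[1], config$mu_range[2])
    while (any(eq <- m2 == mu1[is_de])) {
      m2[eq] <- runif(sum(eq), config$mu_range[1], config$mu_range[2])
    }
    mu2[is_de] <- m2
  } else {
    mu2[is_de] <- mu1[is_de] -
      config$fixed_effect * sample(c(-1, 1), n_de, replace = TRUE)
  }
  x <- cbind(matrix(rnorm(G * n, mu1, config$sigma), G, n),
             matrix(rnorm(G * n, mu2, config$sigma), G, n))
  sim <- structure(
    list(data = values_to_tibble(x, n),
         is_de = is_de,
         outlier_mask = matrix(FALSE, G, 2L * n),
         mu1 = mu1, mu2 = mu2,
         original_values = numeric(0),
         config = config),
    class = "samfc_sim")
  if (config$contamination != "none") sim <- contaminate_dataset(sim)
  sim
}

values_to_tibble <- function(x, n) {
  colnames(x) <- c(paste0("c1_", seq_len(n)), paste0("c2_", seq_len(n)))
  dplyr::bind_cols(tibble(gene_id = sprintf("g%05d", seq_len(nrow(x)))),
                   as_tibble(as.data.frame(x)))
}

sim_values <- function(sim) {
  as.matrix(sim$data[, -1, drop = FALSE])
}

#' Plant one-sided outlying expressions in a simulated dataset
#'
#' For each targeted gene, one (or two) randomly placed expressions are
#' replaced by `x* = d + 2 * max(x_gik over the replicates of the chosen
#' condition)`, the maximum taken over the pre-contamination values, with
#' `d` drawn from `d_range` (or `fixed_d`). Since `d > 0`, every planted
#' value strictly exceeds the condition's previous maximum, so contamination
#' is one-sided and upward. The replaced entries are recorded in
#' `outlier_mask` and their original values kept, so the clean dataset is
#' recoverable.
#'
#' @param sim A `samfc_sim` from [simulate_paired_expression()].
#' @param config Contamination settings; defaults to `sim$config`.
#' @return The contaminated `samfc_sim`.
#' @export
contaminate_dataset <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "samfc_sim"))
  if (any(sim$outlier_mask)) {
    stop("dataset is already contaminated", call. = FALSE)
  }
  if (config$contamination == "none") return(sim)
  x <- sim_values(sim)
  G <- nrow(x)
  n <- config$n
  targets <- if (config$contamination == "all_genes") {
    seq_len(G)
  } else {
    sort(sample.int(G, round(config$outlier_genes_fraction * G)))
  }
  n_out <- if (identical(config$outliers_per_gene, "one_or_two")) {
    sample(1:2, length(targets), replace = TRUE)
  } else {
    rep(as.integer(config$outliers_per_gene), length(targets))
  }
  mask <- sim$outlier_mask
  x_clean <- x
  cond_cols <- list(seq_len(n), n + seq_len(n))
  for (j in seq_along(targets)) {
    g <- targets[j]
    slots <- sample.int(2L * n, n_out[j])
    for (slot in slots) {
      i <- if (slot <= n) 1L else 2L
      cols <- cond_cols[[i]]
      d_shift <- if (is.null(config$fixed_d)) {
        runif(1, config$d_range[1], config$d_range[2])
      } else {
        config$fixed_d
      }
      x_star <- d_shift + 2 * max(x_clean[g, cols])
      x[g, slot] <- x_star
      mask[g, slot] <- TRUE
    }
  }
  sim$data <- values_to_tibble(x, n)
  sim$outlier_mask <- mask
  ## column-major order, matching `x[mask]` indexing, so
  ## `x[mask] <- original_values` restores the clean dataset
  sim$original_values <- x_clean[mask]
  sim
}

#' @export
print.samfc_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated paired expression dataset\n")
  cat(sprintf("  genes: %d (%d DE)   pairs (n): %d   sigma = %g\n",
              cfg$n_genes, sum(x$is_de), cfg$n, cfg$sigma))
  cat(sprintf("  contamination: %s (%d outlying entr%s)\n",
              cfg$contamination, sum(x$outlier_mask),
              if (sum(x$outlier_mask) == 1) "y" else "ies"))
  invisible(x)
}
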