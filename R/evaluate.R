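#' Confusion counts for top-N calling
#'
#' Declares the first `n_top` genes of a ranking differentially expressed and
#' tabulates the four outcomes against the truth labels.
#'
#' @param ranking Gene identifiers (or integer indices into `truth`) ordered
#'   from strongest to weakest evidence.
#' @param truth Logical vector of true DE labels; if `ranking` holds
#'   identifiers, `truth` must be named or parallel to the original gene
#'   order given in `gene_ids`.
#' @param n_top Number of leading genes to call DE.
#' @param gene_ids Gene identifiers parallel to `truth` when `ranking` is a
#'   character vector.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
top_n_confusion <- function(ranking, truth, n_top, gene_ids = NULL) {
  stopifnot(n_top >= 0, n_top <= length(truth))
  if (is.character(ranking)) {
    ids <- gene_ids %||% names(truth)
    if (is.null(ids)) stop("character ranking needs `gene_ids` or named truth",
                           call. = FALSE)
    idx <- match(ranking, ids)
    if (anyNA(idx)) stop("ranking contains unknown gene id(s)", call. = FALSE)
  } else {
    idx <- as.integer(ranking)
  }
  called <- logical(length(truth))
  called[idx[seq_len(n_top)]] <- TRUE
  tibble(tp = sum(called & truth), fp = sum(called & !truth),
         tn = sum(!called & !truth), fn = sum(!called & truth))
}

#' Performance measures from confusion counts
#'
#' Standard definitions: TPR = TP/(TP+FN), TNR = TN/(TN+FP), FPR =
#' FP/(TN+FP), FNR = FN/(TP+FN), FDR = FP/(TP+FP), FOR = FN/(TN+FN), MER =
#' (FP+FN)/total. Under top-N calling with N equal to the number of true DE
#' genes, TP+FP = TP+FN, so FDR and FNR coincide and the precision-flavoured
#' variants of these measures agree with the standard ones. Measures with a
#' zero denominator are reported as `NA` with a warning.
#'
#' @param counts A one-row data frame with `tp`, `fp`, `tn`, `fn` (as from
#'   [top_n_confusion()]).
#' @return A one-row tibble with `tpr`, `tnr`, `fpr`, `fnr`, `fdr`, `for_`,
#'   `mer`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- counts$tp[1]; fp <- counts$fp[1]; tn <- counts$tn[1]; fn <- counts$fn[1]
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting NA", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  tibble(
    tpr = safe(tp, tp + fn, "TPR"),
    tnr = safe(tn, tn + fp, "TNR"),
    fpr = safe(fp, tn + fp, "FPR"),
    fnr = safe(fn, tp + fn, "FNR"),
    fdr = safe(fp, tp + fp, "FDR"),
    for_ = safe(fn, tn + fn, "FOR"),
    mer = safe(fp + fn, tp + fp + tn + fn, "MER")
  )
}

#' ROC curve, AUC and partial AUC of a gene score
#'
#' Traces the ROC over all thresholds of the score (larger = stronger DE
#' evidence; tied scores are grouped so the curve is threshold-faithful),
#' integrates it by the trapezoid rule, and additionally integrates only over
#' `FPR <= fpr_cap` without normalisation, so a perfect classifier attains
#' `pauc = fpr_cap`.
#'
#' @param score Numeric score per gene (larger = more likely DE).
#' @param truth Logical true DE labels.
#' @param fpr_cap Upper FPR limit of the partial area. Default 0.2.
#' @return A list of class `samfc_roc`: `roc` (tibble of `fpr`, `tpr`),
#'   `auc`, `pauc`, `fpr_cap`.
#' @export
roc_auc <- function(score, truth, fpr_cap = 0.2) {
  stopifnot(length(score) == length(truth), fpr_cap > 0, fpr_cap <= 1)
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("both classes must be present to trace a ROC curve", call. = FALSE)
  }
  ord <- order(-score)
  s <- score[ord]; lab <- truth[ord]
  ## group tied scores: cumulative counts at the last row of each tie group
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(lab)[last_of_group]
  fp <- cumsum(!lab)[last_of_group]
  tpr <- c(0, tp / sum(truth))
  fpr <- c(0, fp / sum(!truth))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  ## partial area over [0, fpr_cap], interpolating the cap point
  tpr_cap <- approx(fpr, tpr, xout = fpr_cap, ties = "ordered")$y
  keep <- fpr < fpr_cap
  fpr_p <- c(fpr[keep], fpr_cap)
  tpr_p <- c(tpr[keep], tpr_cap)
  pauc <- sum(diff(fpr_p) * (head(tpr_p, -1) + tail(tpr_p, -1)) / 2)
  structure(list(roc = tibble(fpr = fpr, tpr = tpr), auc = auc, pauc = pauc,
                 fpr_cap = fpr_cap),
            class = "samfc_roc")
}

#' @export
print.samfc_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f, pAUC(FPR <= %g) = %.4f\n",
              x$auc, x$fpr_cap, x$pauc))
  invisible(x)
}

#' @method autoplot samfc_roc
#' @export
autoplot.samfc_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_vline(xintercept = object$fpr_cap, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f, pAUC = %.3f", object$auc,
                                  object$pauc)) +
    ggplot2::theme_minimal()
}

#' Baseline gene rankings: paired t-test and Wilcoxon signed rank
#'
#' Simple per-gene comparators operating on the paired differences.
#' `"t_test"` is the classical one-sample t with Student-t p-values.
#' `"wilcoxon"` is the exact one-sample signed-rank test (zeros dropped,
#' normal approximation when ties or zeros make the exact null unavailable),
#' reported as the statistic centred at its null mean `m(m+1)/4`. Genes are
#' ranked by ascending p-value, then descending `|statistic|`, then
#' descending `|mean difference|` (the magnitude evidence that
#' disambiguates the coarse p-value ties of small n), then gene identifier.
#'
#' @param diffs Differences as produced by [compute_differences()].
#' @param method `"t_test"` or `"wilcoxon"`.
#' @return A tibble `gene_id`, `statistic`, `p_value`, `rank`, ordered by
#'   rank.
#' @export
baseline_rankings <- function(diffs, method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  dm <- diffs_to_matrix(diffs)
  d <- dm$d
  n <- ncol(d)
  stopifnot(n >= 2)
  mean_d <- rowMeans(d)
  if (method == "t_test") {
    sd_d <- sqrt(rowSums((d - mean_d)^2) / (n - 1L))
    stat <- ifelse(sd_d == 0, sign(mean_d) * Inf,
                   mean_d / (sd_d / sqrt(n)))
    pv <- ifelse(is.infinite(stat), 0, 2 * pt(-abs(stat), df = n - 1L))
    pv[is.infinite(stat) & mean_d == 0] <- 1
  } else {
    res <- signed_rank_rows(d)
    stat <- res$centered
    pv <- res$p
  }
  ord <- order(pv, -abs(stat), -abs(mean_d), dm$gene_id)
  tibble(gene_id = dm$gene_id, statistic = stat, p_value = pv)[ord, ] |>
    mutate(rank = row_number())
}

## Vectorised one-sample signed-rank test over the rows of d.
## Zeros are dropped (Wilcoxon's convention); exact p from psignrank when
## there are no ties among |d|, else a normal approximation with continuity
## correction.
signed_rank_rows <- function(d) {
  n_row <- nrow(d)
  V <- numeric(n_row); p <- numeric(n_row); centered <- numeric(n_row)
  abs_d <- abs(d)
  for (g in seq_len(n_row)) {
    dg <- d[g, ]
    dg <- dg[dg != 0]
    m <- length(dg)
    if (m == 0) {
      V[g] <- 0; centered[g] <- 0; p[g] <- 1
      next
    }
    r <- rank(abs(dg))
    v <- sum(r[dg > 0])
    V[g] <- v
    centered[g] <- v - m * (m + 1) / 4
    if (anyDuplicated(r) == 0) {
      p[g] <- min(1, 2 * min(psignrank(v, m), psignrank(v - 1, m,
                                                        lower.tail = FALSE)))
    } else {
      mu <- m * (m + 1) / 4
      tie_tab <- table(r)
      sig2 <- m * (m + 1) * (2 * m + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
      p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(V = V, centered = centered, p = p)
}

#' Simulation experiment over repeated datasets
#'
#' Generates `n_datasets` seeded datasets from `config` (contaminating them
#' when the config says so), scores every gene with each requested method,
#' computes top-N confusion metrics (N defaulting to the number of true DE
#' genes) plus AUC and partial AUC of the full ranking, and averages across
#' datasets.
#'
#' Methods: `"proposed"` (the hybrid robust SAM-FC average rank),
#' `"classical_sam"` (the same pipeline with beta = 0, i.e. no robustness),
#' `"t_test"`, `"wilcoxon"`.
#'
#' @param config A [simulation_config()]; its `seed` is combined with
#'   dataset index and the experiment `seed`.
#' @param n_datasets Number of datasets.
#' @param methods Character vector of method names.
#' @param seed Master seed of the experiment.
#' @param n_top Genes called per dataset; default = number of true DE genes.
#' @param fpr_cap Partial-AUC cap. Default 0.2.
#' @param fit_args Extra arguments passed to [samfc()] for the proposed /
#'   classical methods.
#' @return A tibble with one row per method: averaged `tpr`, `fpr`, `tnr`,
#'   `fnr`, `fdr`, `for_`, `mer`, `auc`, `pauc` and their Monte-Carlo
#'   standard errors (`*_se`), with `n_datasets` recorded.
#' @export
run_experiment <- function(config, n_datasets = 10L,
                           methods = c("proposed", "t_test", "wilcoxon"),
                           seed = 1L, n_top = NULL, fpr_cap = 0.2,
                           fit_args = list()) {
  stopifnot(inherits(config, "simulation_config"), n_datasets >= 1)
  methods <- match.arg(methods,
                       c("proposed", "classical_sam", "t_test", "wilcoxon"),
                       several.ok = TRUE)
  set.seed(seed)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  per_method <- lapply(setNames(methods, methods), function(m) vector("list", n_datasets))
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- dataset_seeds[i]
    sim <- simulate_paired_expression(cfg)
    truth <- sim$is_de
    ntop_i <- n_top %||% sum(truth)
    diffs <- compute_differences(sim$data)
    for (m in methods) {
      score <- method_score(m, sim, diffs, fit_args)
      conf <- top_n_confusion(order(-score), truth, ntop_i)
      met <- compute_metrics(conf)
      roc <- roc_auc(score, truth, fpr_cap)
      per_method[[m]][[i]] <- mutate(met, auc = roc$auc, pauc = roc$pauc)
    }
  }
  rows <- lapply(methods, function(m) {
    all_i <- bind_rows(per_method[[m]])
    means <- dplyr::summarise(all_i, across(dplyr::everything(), mean))
    ses <- dplyr::summarise(all_i, across(dplyr::everything(),
                                          ~ sd(.x) / sqrt(length(.x))))
    names(ses) <- paste0(names(ses), "_se")
    dplyr::bind_cols(tibble(method = m, n_datasets = n_datasets), means, ses)
  })
  bind_rows(rows)
}

## Larger score = stronger DE evidence, for each method.
method_score <- function(method, sim, diffs, fit_args = list()) {
  switch(
    method,
    proposed = {
      args <- c(list(data = sim$data, pvalue_method = "t_reference",
                     seed = sim$config$seed), fit_args)
      fit <- do.call(samfc, args)
      score_from_fit(fit, sim$data$gene_id)
    },
    classical_sam = {
      args <- c(list(data = sim$data, beta = 0, pvalue_method = "t_reference",
                     seed = sim$config$seed), fit_args)
      fit <- do.call(samfc, args)
      score_from_fit(fit, sim$data$gene_id)
    },
    t_test = ,
    wilcoxon = {
      rk <- baseline_rankings(diffs, method)
      -rk$rank[match(sim$data$gene_id, rk$gene_id)]
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

## The pipeline's ranking score: negative average rank in original gene order
## (sam_rank breaks exact avg-rank ties, mirroring the selection ordering).
score_from_fit <- function(fit, gene_order) {
  sc <- fit$scores
  idx <- match(gene_order, sc$gene_id)
  -(sc$avg_rank[idx] + sc$sam_rank[idx] / (2 * length(idx)))
}
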