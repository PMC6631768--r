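#' Construct a paired two-condition expression experiment
#'
#' Validates a genes x samples table of (log-scale) expression values together
#' with a pairing scheme that maps each replicate pair to one condition-1
#' column and one condition-2 column. All downstream analysis operates on the
#' per-gene vector of paired differences `d_gk = x_g1k - x_g2k`.
#'
#' @param data A data frame with gene identifiers in `gene_col` and one
#'   numeric column per sample, or a numeric matrix with rownames.
#' @param pairs Pairing scheme: a two-column matrix or data frame whose rows
#'   are (condition-1 column, condition-2 column), given as column names or
#'   integer positions among the sample columns. `NULL` (default) pairs the
#'   first half of the sample columns with the second half in order, so a
#'   6-column table yields pairs (1,4), (2,5), (3,6).
#' @param gene_col Column holding gene identifiers (name or position).
#'
#' @details Values are analysed on the scale supplied; fold-change semantics
#'   assume log-scale input (so a paired difference is a log fold change), but
#'   this is documented rather than enforced. No normalisation is applied.
#'
#' @return An object of class `paired_exp`: a list with `gene_ids`, `values`
#'   (genes x samples numeric matrix), `pairs` (n x 2 integer matrix of column
#'   indices), and `n` (replicate pairs per condition).
#' @examples
#' df <- data.frame(gene = c("g1", "g2"),
#'                  t1 = c(5, 3), t2 = c(6, 3),
#'                  c1 = c(3, 3), c2 = c(2, 3))
#' pe <- paired_experiment(df)
#' pe$n
#' @export
paired_experiment <- function(data, pairs = NULL, gene_col = 1L) {
  if (is.matrix(data)) {
    if (is.null(rownames(data))) {
      stop("matrix input requires rownames as gene identifiers", call. = FALSE)
    }
    gene_ids <- rownames(data)
    values <- unname(data)
    sample_names <- colnames(data) %||% paste0("s", seq_len(ncol(data)))
  } else {
    data <- as.data.frame(data)
    gidx <- if (is.character(gene_col)) match(gene_col, names(data)) else as.integer(gene_col)
    if (is.na(gidx) || gidx < 1L || gidx > ncol(data)) {
      stop("`gene_col` does not identify a column of `data`", call. = FALSE)
    }
    gene_ids <- as.character(data[[gidx]])
    value_df <- data[, -gidx, drop = FALSE]
    bad_type <- names(value_df)[!vapply(value_df, is.numeric, logical(1))]
    if (length(bad_type) > 0) {
      stop("non-numeric sample column(s): ", paste(bad_type, collapse = ", "),
           call. = FALSE)
    }
    values <- as.matrix(value_df)
    sample_names <- colnames(value_df)
    values <- unname(values)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene identifier(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_names[bad[2]]), call. = FALSE)
  }
  pairs <- resolve_pairs(pairs, sample_names, ncol(values))
  structure(
    list(gene_ids = gene_ids, values = values, pairs = pairs,
         n = nrow(pairs), sample_names = sample_names),
    class = "paired_exp"
  )
}

resolve_pairs <- function(pairs, sample_names, n_samples) {
  if (is.null(pairs)) {
    if (n_samples %% 2L != 0L) {
      stop("odd number of sample columns (", n_samples, "); supply `pairs` ",
           "explicitly to declare the pairing", call. = FALSE)
    }
    n <- n_samples %/% 2L
    pairs <- cbind(seq_len(n), n + seq_len(n))
  } else {
    pairs <- as.matrix(as.data.frame(pairs))
    if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
    if (is.character(pairs)) {
      idx <- matrix(match(pairs, sample_names), ncol = 2L)
      if (anyNA(idx)) {
        missing_nm <- pairs[is.na(idx)]
        stop("unknown sample name(s) in `pairs`: ",
             paste(unique(missing_nm), collapse = ", "), call. = FALSE)
      }
      pairs <- idx
    } else {
      storage.mode(pairs) <- "integer"
    }
  }
  used <- as.vector(pairs)
  if (anyNA(used) || any(used < 1L) || any(used > n_samples)) {
    stop("pair indices out of range 1..", n_samples, call. = FALSE)
  }
  if (anyDuplicated(used)) {
    bad <- used[duplicated(used)][1]
    offending <- which(pairs == bad, arr.ind = TRUE)[, 1]
    stop(sprintf("column %d appears in more than one pair slot (pairs %s)",
                 bad, paste(offending, collapse = " and ")), call. = FALSE)
  }
  if (nrow(pairs) < 2L) {
    stop("need at least 2 replicate pairs (variance is not estimable)",
         call. = FALSE)
  }
  unname(pairs)
}

#' @export
print.paired_exp <- function(x, ...) {
  cat("Paired expression experiment\n")
  cat("  genes:    ", length(x$gene_ids), "\n")
  cat("  pairs (n):", x$n, "\n")
  invisible(x)
}

#' Per-gene paired differences
#'
#' Forms, for every gene, the vector of paired differences
#' `d_k = x[condition-1 column of pair k] - x[condition-2 column of pair k]`.
#' On log-scale input each `d_k` is a per-pair log fold change.
#'
#' @param data A `paired_exp`, or a data frame / matrix accepted by
#'   [paired_experiment()].
#' @inheritParams paired_experiment
#' @return A tibble with `gene_id` and columns `d1 ... dn`, one row per gene.
#' @examples
#' df <- data.frame(gene = "g1", a = 5, b = 6, c = 3, d = 2)
#' compute_differences(df)
#' @export
compute_differences <- function(data, pairs = NULL, gene_col = 1L) {
  pe <- as_paired_exp(data, pairs, gene_col)
  d <- diff_matrix(pe)
  out <- as_tibble(as.data.frame(d))
  names(out) <- paste0("d", seq_len(ncol(d)))
  dplyr::bind_cols(tibble(gene_id = pe$gene_ids), out)
}

as_paired_exp <- function(data, pairs = NULL, gene_col = 1L) {
  if (inherits(data, "paired_exp")) data else paired_experiment(data, pairs, gene_col)
}

diff_matrix <- function(pe) {
  pe$values[, pe$pairs[, 1], drop = FALSE] - pe$values[, pe$pairs[, 2], drop = FALSE]
}

## Extract the numeric difference matrix from a compute_differences() tibble,
## a plain data frame of d-columns, or a numeric matrix.
diffs_to_matrix <- function(diffs) {
  if (is.matrix(diffs)) {
    return(list(d = diffs,
                gene_id = rownames(diffs) %||% paste0("g", seq_len(nrow(diffs)))))
  }
  diffs <- as.data.frame(diffs)
  has_id <- "gene_id" %in% names(diffs)
  gene_id <- if (has_id) as.character(diffs$gene_id) else paste0("g", seq_len(nrow(diffs)))
  d <- as.matrix(diffs[, setdiff(names(diffs), "gene_id"), drop = FALSE])
  if (!is.numeric(d)) stop("difference columns must be numeric", call. = FALSE)
  list(d = unname(d), gene_id = gene_id)
}

#' Read a genes x samples expression matrix from delimited text
#'
#' Expects a header row of sample names and a first column of unique gene
#' identifiers. The delimiter is taken from the file extension (`.csv` =>
#' comma, otherwise tab). Lines starting with `#` are treated as metadata and
#' skipped. Non-numeric or missing cells are rejected with their location.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param pairs Pairing scheme passed to [paired_experiment()].
#' @return A `paired_exp` object.
#' @export
read_expression_matrix <- function(path, pairs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (ncol(raw) < 3L) stop("expected a gene-id column plus sample columns", call. = FALSE)
  gene_ids <- raw[[1]]
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(raw)[-1]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row %d (gene '%s'), column '%s'",
                 bad[1], gene_ids[bad[1]], colnames(num)[bad[2]]), call. = FALSE)
  }
  df <- data.frame(gene_id = gene_ids, num, check.names = FALSE)
  paired_experiment(df, pairs = pairs, gene_col = 1L)
}

#' Write a per-gene results table as tab-delimited text
#'
#' Writes the score table of a [samfc()] fit (or any data frame) with
#' `#`-prefixed metadata header lines recording the run parameters, so a
#' result file is self-describing and reproducible.
#'
#' @param x A `samfc_fit` or a data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  meta <- character()
  if (inherits(x, "samfc_fit")) {
    p <- x$params
    meta <- c(
      sprintf("# samfc results"),
      sprintf("# beta=%g alpha=%g delta_cap=%g", p$beta, p$alpha, p$delta_cap),
      sprintf("# delta=%.6g s0=%.6g n=%d", x$delta, x$s0, p$n),
      sprintf("# pvalue_method=%s seed=%s", p$pvalue_method, format(p$seed)),
      sprintf("# n_outlying=%d n_selected=%d", sum(x$scores$is_outlying_gene),
              sum(x$scores$selected))
    )
    x <- x$scores
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(meta, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a tab-delimited results file.
#' @return A tibble.
#' @export
read_results <- function(path) {
  as_tibble(utils::read.delim(path, comment.char = "#", check.names = FALSE,
                              stringsAsFactors = FALSE))
}
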