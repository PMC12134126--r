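#' Expression tables
#'
#' Expression data travel through the package as a tibble whose first column
#' is `gene_id` and whose remaining columns are numeric sample values
#' (genes in rows, samples in columns).  The measurement scale is tracked in
#' the `"expr_scale"` attribute: `"linear"` (FPKM-like, non-negative),
#' `"log2"`, or `"zscore"` (each gene row has mean 0 and sample sd 1).
#'
#' @param expr expression tibble.
#' @name expression-tables
NULL

#' @rdname expression-tables
#' @export
expr_scale <- function(expr) {
  attr(expr, "expr_scale") %||% "linear"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_expr_scale <- function(expr, scale) {
  attr(expr, "expr_scale") <- scale
  expr
}

## tibble (gene_id + sample columns) -> numeric matrix with gene rownames
expr_mat <- function(expr) {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    arg_error("Expression input must be a data frame with a `gene_id` column.")
  }
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m)) arg_error("All sample columns must be numeric.")
  if (anyNA(m)) arg_error("Expression values must not contain missing values.")
  rownames(m) <- expr$gene_id
  m
}

expr_tbl <- function(mat, scale) {
  out <- as_tibble(mat, rownames = NA)
  out <- tibble::add_column(out, gene_id = rownames(mat), .before = 1)
  set_expr_scale(out, scale)
}

#' Convert a linear-scale expression table to log2
#'
#' @param expr linear-scale expression tibble.
#' @param offset pseudo-value added before taking logs; the default 0 assumes
#'   strictly positive values (as emitted by the simulators).
#' @return log2-scale expression tibble.
#' @export
to_log2 <- function(expr, offset = 0) {
  m <- expr_mat(expr)
  if (any(m + offset <= 0)) {
    arg_error("Values must be positive after adding `offset` to take log2.")
  }
  expr_tbl(log2(m + offset), "log2")
}

#' Select highly variable genes
#'
#' Ranks genes by the sample variance of their log2 expression across all
#' samples and returns the `n` most variable, the first filter of the DEL
#' identification procedure.  Ties are broken by `gene_id` ascending so the
#' selection is fully deterministic.
#'
#' @param expr log2-scale expression tibble.
#' @param n number of genes to keep (default 1000).
#' @return Character vector of `n` gene ids, ordered by decreasing variance.
#' @export
select_hvg <- function(expr, n = 1000) {
  if (length(n) != 1 || !is.finite(n) || n <= 0) {
    arg_error("`n` must be a positive count.")
  }
  if (identical(expr_scale(expr), "linear")) {
    arg_error("`select_hvg()` expects log2-scale input; see `to_log2()`.")
  }
  m <- expr_mat(expr)
  if (n > nrow(m)) arg_error("`n` exceeds the number of genes.")
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Z-score expression rows
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation
#' (n - 1 denominator) 1.  Constant rows carry no spatial information and are
#' dropped with a warning.
#'
#' @param expr log2-scale expression tibble.
#' @return z-score-scale expression tibble (possibly with fewer rows).
#' @export
zscore_rows <- function(expr) {
  m <- expr_mat(expr)
  sds <- apply(m, 1, sd)
  drop <- sds == 0
  if (all(drop)) abort("All rows are constant; nothing to z-score.",
                       class = "delatlas_empty_error")
  if (any(drop)) {
    warn(sprintf("Dropping %d constant row(s) during z-scoring: %s",
                 sum(drop), paste(head(rownames(m)[drop], 5), collapse = ", ")))
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  z <- (m - rowMeans(m)) / sds
  expr_tbl(z, "zscore")
}

## restrict an expression tibble to a gene set, preserving scale
filter_genes <- function(expr, genes) {
  keep <- expr$gene_id %in% genes
  set_expr_scale(expr[keep, , drop = FALSE], expr_scale(expr))
}
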