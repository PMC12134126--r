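#' Pairwise differential calls between preliminary domains
#'
#' For every unordered pair of preliminary domains and every gene, computes a
#' two-sided Welch t-test on log2 values and a linear-scale fold change
#' `FC = (mean_A + eps) / (mean_B + eps)`.  A gene is called for a pair iff
#' `p < p_thresh` and `max(FC, 1/FC) >= fc_thresh`; the gate is
#' direction-agnostic.  No multiple-testing correction is applied by default
#' (the procedure uses raw P < 0.05); Benjamini-Hochberg correction across
#' all gene-pair tests can be switched on.
#'
#' @param expr linear-scale expression tibble (strictly positive values).
#' @param partition preliminary-domain partition tibble (sample_id, domain);
#'   every domain needs >= 2 samples.
#' @param p_thresh t-test p-value threshold (default 0.05).
#' @param fc_thresh linear fold-change threshold (default 1.5).
#' @param eps pseudocount added to linear domain means (default 1e-6).
#' @param adjust "none" (default) or "BH".
#' @return Tibble of calls: gene_id, source = "ttest_fc", domain_a, domain_b,
#'   p_value, fold_change (the direction-agnostic max(FC, 1/FC)).
#' @export
pairwise_del <- function(expr, partition, p_thresh = 0.05, fc_thresh = 1.5,
                         eps = 1e-6, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- expr_mat(expr)
  if (any(m < 0)) arg_error("`pairwise_del()` expects linear-scale values.")
  groups <- partition_groups(partition, colnames(m))
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    abort(sprintf("Domain(s) with < 2 samples: %s",
                  paste(names(groups)[sizes < 2], collapse = ", ")),
          class = "delatlas_partition_error")
  }
  lg <- log2(pmax(m, .Machine$double.xmin))
  doms <- names(groups)
  stats_per_dom <- lapply(groups, function(idx) {
    sub <- lg[, idx, drop = FALSE]
    list(n = length(idx),
         mean_log = rowMeans(sub),
         var_log = apply(sub, 1, var),
         mean_lin = rowMeans(m[, idx, drop = FALSE]))
  })
  res <- list()
  for (a in seq_along(doms)) {
    for (b in seq_along(doms)) {
      if (b <= a) next
      sa <- stats_per_dom[[a]]; sb <- stats_per_dom[[b]]
      p <- welch_p(sa$mean_log, sa$var_log, sa$n, sb$mean_log, sb$var_log, sb$n)
      fc <- (sa$mean_lin + eps) / (sb$mean_lin + eps)
      res[[paste(a, b)]] <- tibble(gene_id = rownames(m), source = "ttest_fc",
                                   domain_a = doms[a], domain_b = doms[b],
                                   p_value = unname(p),
                                   fold_change = unname(pmax(fc, 1 / fc)))
    }
  }
  calls <- dplyr::bind_rows(res)
  if (adjust == "BH") calls$p_value <- stats::p.adjust(calls$p_value, "BH")
  calls <- calls[!is.na(calls$p_value) & calls$p_value < p_thresh &
                   calls$fold_change >= fc_thresh, , drop = FALSE]
  dplyr::arrange(calls, .data$gene_id, .data$domain_a, .data$domain_b)
}

## vectorized two-sided Welch t over gene rows; zero pooled variance with a
## mean difference counts as p = 0, with equal means as p = 1
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2 ^ 2 / ((v1 / n1) ^ 2 / (n1 - 1) + (v2 / n2) ^ 2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Principal component analysis of z-scored expression
#'
#' PCA with samples as observations and z-scored genes as variables.
#' Loadings (gene x PC) are orthonormal, components are ordered by
#' decreasing variance explained, and each loading vector is sign-fixed so
#' that its largest-magnitude entry is positive.
#'
#' @param expr z-score-scale expression tibble.
#' @return A `del_pca` list: `loadings` (genes x PC), `scores`
#'   (samples x PC), `var_explained`.
#' @export
run_pca <- function(expr) {
  m <- expr_mat(expr)
  if (ncol(m) < 2) arg_error("PCA needs >= 2 samples.")
  if (all(m == 0)) abort("Degenerate (rank-0) input.", class = "delatlas_rank_error")
  pc <- prcomp(t(m), center = FALSE, scale. = FALSE)
  keep <- pc$sdev > 1e-12 * pc$sdev[1]
  loadings <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = loadings, scores = scores,
                 var_explained = pc$sdev[keep] ^ 2 / sum(pc$sdev ^ 2)),
            class = "del_pca")
}

#' Jackstraw significance of principal components
#'
#' In each of `B` iterations a random fraction `s` of gene rows is permuted
#' across samples and the PCA recomputed; the absolute loadings of the
#' permuted genes are pooled per PC as the empirical null.  Each observed
#' gene loading gets an empirical p-value
#' `(1 + #null >= |loading|) / (1 + #null)`.  A PC is declared significant
#' when the fraction of genes with p < 0.05 exceeds 0.05 by a one-sided
#' binomial test, Bonferroni-corrected across the `n_pcs` PCs examined so
#' the family-wise false-positive rate stays at `alpha`.
#'
#' @param expr z-score-scale expression tibble.
#' @param n_pcs number of leading PCs to assess.
#' @param s fraction of genes permuted per iteration (0 < s < 1).
#' @param B number of permutation iterations.
#' @param alpha family-wise significance level for PC calls.
#' @param seed integer RNG seed.
#' @return A `jackstraw_result` list: `per_gene_p` (genes x PC matrix),
#'   `significant_pcs`, `pc_pvalues`, plus the `s`, `B`, `alpha` settings.
#' @export
jackstraw_pcs <- function(expr, n_pcs = 4, s = 0.1, B = 100, alpha = 0.05,
                          seed = 1) {
  m <- expr_mat(expr)
  G <- nrow(m)
  n_perm <- floor(s * G)
  if (s <= 0 || s >= 1 || n_perm < 1) {
    arg_error("`s` must satisfy 0 < s < 1 with s * genes >= 1.")
  }
  max_pcs <- min(G, ncol(m)) - 1
  if (n_pcs > max_pcs) arg_error("`n_pcs` exceeds min(genes, samples) - 1.")
  obs <- abs(run_pca(expr_tbl(m, "zscore"))$loadings[, seq_len(n_pcs),
                                                     drop = FALSE])
  null <- withr::with_seed(seed, {
    acc <- vector("list", B)
    for (b in seq_len(B)) {
      idx <- sample.int(G, n_perm)
      mp <- m
      for (i in idx) mp[i, ] <- mp[i, sample.int(ncol(m))]
      pc <- prcomp(t(mp), center = FALSE, scale. = FALSE)
      acc[[b]] <- abs(pc$rotation[idx, seq_len(n_pcs), drop = FALSE])
    }
    do.call(rbind, acc)
  })
  per_gene_p <- matrix(NA_real_, G, n_pcs,
                       dimnames = list(rownames(m), paste0("PC", seq_len(n_pcs))))
  for (j in seq_len(n_pcs)) {
    sn <- sort(null[, j])
    N <- length(sn)
    n_less <- findInterval(obs[, j], sn, left.open = TRUE)
    per_gene_p[, j] <- (1 + (N - n_less)) / (1 + N)
  }
  counts <- colSums(per_gene_p < 0.05)
  pc_pvalues <- pbinom(counts - 1, G, 0.05, lower.tail = FALSE)
  significant <- which(pc_pvalues < alpha / n_pcs)
  structure(list(s = s, B = B, alpha = alpha, per_gene_p = per_gene_p,
                 pc_pvalues = pc_pvalues,
                 significant_pcs = as.integer(significant)),
            class = "jackstraw_result")
}

#' Top and bottom PC-loading genes as DEL calls
#'
#' For each requested PC, takes the `top_n / 2` most-positive and
#' `top_n / 2` most-negative loading genes ("top highest and lowest");
#' alternatively the `top_n` genes by absolute loading.  Duplicate genes
#' across PCs are retained as separate calls.
#'
#' @param pca a [run_pca()] result.
#' @param pcs PC indices to harvest (e.g. jackstraw-significant PCs, or the
#'   fixed 1:4).
#' @param top_n genes per PC (even; clipped with a warning if it exceeds the
#'   gene count).
#' @param by_magnitude take `top_n` by |loading| instead of the
#'   half-positive/half-negative split.
#' @return Tibble of calls: gene_id, source = "pc_loading", pc, loading.
#' @export
pc_loading_genes <- function(pca, pcs = 1:4, top_n = 300,
                             by_magnitude = FALSE) {
  stopifnot(inherits(pca, "del_pca"))
  bad <- setdiff(pcs, seq_len(ncol(pca$loadings)))
  if (length(bad) > 0) arg_error("Requested PCs not present in the PCA.")
  G <- nrow(pca$loadings)
  if (top_n > G) {
    warn(sprintf("`top_n` (%d) exceeds gene count (%d); clipping.", top_n, G))
    top_n <- if (G %% 2 == 0) G else G - 1
  }
  if (top_n %% 2 != 0 && !by_magnitude) arg_error("`top_n` must be even.")
  gid <- rownames(pca$loadings)
  out <- lapply(pcs, function(j) {
    l <- pca$loadings[, j]
    if (by_magnitude) {
      pick <- order(-abs(l), gid)[seq_len(top_n)]
    } else {
      pos <- order(-l, gid)[seq_len(top_n / 2)]
      neg <- order(l, gid)[seq_len(top_n / 2)]
      pick <- c(pos, neg)
    }
    tibble(gene_id = gid[pick], source = "pc_loading", pc = j,
           loading = unname(l[pick]))
  })
  dplyr::bind_rows(out)
}

#' Combine t-test/fold-change and PC-loading calls into a DEL set
#'
#' @param ttest_calls calls from [pairwise_del()].
#' @param pc_calls calls from [pc_loading_genes()].
#' @param mode "union" (default) keeps every gene called by either source;
#'   "intersection" keeps genes supported by both.
#' @return A `del_set` object with elements `calls` (all retained calls) and
#'   `genes` (deduplicated, sorted gene ids).
#' @export
combine_dels <- function(ttest_calls, pc_calls,
                         mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  t_genes <- unique(ttest_calls$gene_id)
  p_genes <- unique(pc_calls$gene_id)
  genes <- if (mode == "union") union(t_genes, p_genes) else
    intersect(t_genes, p_genes)
  genes <- sort(genes)
  calls <- dplyr::bind_rows(
    ttest_calls[ttest_calls$gene_id %in% genes, , drop = FALSE],
    pc_calls[pc_calls$gene_id %in% genes, , drop = FALSE])
  structure(list(calls = calls, genes = genes, mode = mode),
            class = "del_set")
}

#' @export
print.del_set <- function(x, ...) {
  cat(sprintf("<del_set> %d genes from %d calls (mode = %s)\n",
              length(x$genes), nrow(x$calls), x$mode))
  invisible(x)
}

#' @rdname combine_dels
#' @param x a `del_set`.
#' @param ... unused.
#' @method tidy del_set
#' @export
tidy.del_set <- function(x, ...) as_tibble(x$calls)
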