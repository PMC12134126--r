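#' Preliminary spatial domains by hierarchical clustering
#'
#' Clusters samples with average-linkage hierarchical clustering on the
#' correlation distance `1 - Pearson(sample_i, sample_j)` computed over the
#' z-scored highly variable genes, and cuts the dendrogram into exactly
#' `k_prelim` clusters.  The visually "distinctly separated dendrogram" of
#' the original procedure is operationalized as this explicit cut; a natural
#' default for `k_prelim` is the number of distinct zipcodes in the sample
#' metadata.
#'
#' @param expr z-score-scale expression tibble (genes x samples).
#' @param k_prelim number of preliminary domains.
#' @return A partition tibble (sample_id, domain) with attributes `K` and
#'   `kind = "preliminary"`.
#' @export
preliminary_domains <- function(expr, k_prelim) {
  m <- expr_mat(expr)
  if (k_prelim < 1 || k_prelim > ncol(m)) {
    arg_error("`k_prelim` must lie in [1, number of samples].")
  }
  d <- stats::as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = k_prelim)
  partition_tbl(colnames(m), cl, kind = "preliminary", prefix = "P")
}

partition_tbl <- function(sample_id, cluster, kind, prefix) {
  lab <- paste0(prefix, as.integer(factor(cluster, levels = unique(cluster))))
  out <- tibble(sample_id = sample_id, domain = lab)
  attr(out, "K") <- length(unique(lab))
  attr(out, "kind") <- kind
  out
}

#' Final spatial domains by K-means on DEL profiles
#'
#' K-means clustering of the samples in the space of z-scored DEL gene
#' profiles; the best of `n_init` random restarts (by within-cluster sum of
#' squares) is kept and the run is seed-deterministic.
#'
#' @param expr z-score-scale expression tibble restricted to the DEL genes.
#' @param k_final number of spatial domains.
#' @param seed integer RNG seed.
#' @param n_init number of random restarts.
#' @return A partition tibble (sample_id, domain) with attributes `K` and
#'   `kind = "final"`.
#' @export
final_domains <- function(expr, k_final, seed = 1, n_init = 50) {
  m <- expr_mat(expr)
  if (k_final <= 0) arg_error("`k_final` must be positive.")
  if (k_final > ncol(m)) arg_error("`k_final` exceeds the number of samples.")
  km <- withr::with_seed(seed, {
    kmeans(t(m), centers = k_final, nstart = n_init, iter.max = 300)
  })
  partition_tbl(colnames(m), km$cluster, kind = "final", prefix = "D")
}

## validate a partition against an expression matrix and return a
## named list of sample-index vectors per domain
partition_groups <- function(partition, sample_ids) {
  missing <- setdiff(sample_ids, partition$sample_id)
  if (length(missing) > 0) {
    arg_error(sprintf("Samples missing from partition: %s",
                      paste(head(missing, 5), collapse = ", ")))
  }
  dom <- partition$domain[match(sample_ids, partition$sample_id)]
  split(seq_along(sample_ids), dom)
}
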