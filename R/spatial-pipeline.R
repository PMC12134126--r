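#' Full spatial DEL identification pipeline
#'
#' Runs the four-step DEL procedure end to end on one stage's expression
#' table: (1) highly variable gene selection by log2 variance; (2)
#' average-linkage hierarchical clustering on correlation distance to obtain
#' preliminary domains; (3) pairwise Welch-t / fold-change calls between
#' preliminary domains; (4) top positive and negative PC-loading genes from
#' jackstraw-significant PCs.  Step 4 is read as a refinement of step 3, so
#' by default the DEL set is the intersection of the two call sources (the
#' t/FC route provides sensitivity, the PC route specificity); K-means on the DEL profiles yields the final
#' spatial domains, and BIC-selected spherical K-means groups the DEL genes.
#'
#' @param expr linear-scale expression tibble.
#' @param meta sample metadata tibble (sample_id, zipcode, ...); used for the
#'   default `k_prelim`/`k_final` (number of distinct zipcodes).
#' @param n_hvg highly variable genes to keep (clipped to the gene count).
#' @param k_prelim preliminary domain count; default: distinct zipcodes.
#' @param p_thresh,fc_thresh,eps step-3 gates, see [pairwise_del()].
#' @param n_pcs PCs assessed by jackstraw.
#' @param pcs fixed PC indices for step 4, or `NULL` (default) to use the
#'   jackstraw-significant PCs.
#' @param top_n loading genes per PC, see [pc_loading_genes()].
#' @param combine how the two call sources define the DEL set:
#'   "intersection" (default) treats step 4 as a refinement of step 3 so a
#'   DEL needs support from both routes; "union" keeps genes called by
#'   either.
#' @param k_final final domain count; default: distinct zipcodes.
#' @param k_range candidate gene-group counts for BIC-SKmeans.
#' @param seed integer RNG seed (jackstraw, K-means, SKmeans streams are
#'   derived from it).
#' @param n_init K-means / SKmeans restarts.
#' @param jackstraw_B jackstraw permutation iterations.
#' @return A `spatial_del_fit` object bundling the HVG list, preliminary and
#'   final partitions, both call tables, the jackstraw result, the DEL set
#'   and the gene-group clustering.  `tidy()` returns the DEL calls,
#'   `glance()` a one-row summary, `autoplot()` the BIC curve.
#' @export
spatial_del_pipeline <- function(expr, meta, n_hvg = 1000, k_prelim = NULL,
                                 p_thresh = 0.05, fc_thresh = 1.5,
                                 eps = 1e-6, n_pcs = 4, pcs = NULL,
                                 top_n = 300, combine = "intersection",
                                 k_final = NULL, k_range = 2:12, seed = 1,
                                 n_init = 50, jackstraw_B = 100) {
  lg <- to_log2(expr)
  n_hvg <- min(n_hvg, nrow(expr))
  hvg <- select_hvg(lg, n_hvg)
  z <- zscore_rows(filter_genes(lg, hvg))
  if (is.null(k_prelim)) k_prelim <- dplyr::n_distinct(meta$zipcode)
  if (is.null(k_final)) k_final <- dplyr::n_distinct(meta$zipcode)
  prelim <- preliminary_domains(z, k_prelim)
  ## a dendrogram cut can isolate single samples, which the pairwise t-test
  ## cannot use; back off to the largest cut where every domain is testable
  while (min(table(prelim$domain)) < 2 && k_prelim > 2) {
    k_prelim <- k_prelim - 1
    prelim <- preliminary_domains(z, k_prelim)
  }
  ttest_calls <- pairwise_del(filter_genes(expr, hvg), prelim,
                              p_thresh = p_thresh, fc_thresh = fc_thresh,
                              eps = eps)
  pca <- run_pca(z)
  n_pcs <- min(n_pcs, min(nrow(z), ncol(z) - 1) - 1)
  js <- jackstraw_pcs(z, n_pcs = n_pcs, B = jackstraw_B,
                      seed = derive_seed(seed, 1))
  use_pcs <- pcs %||% js$significant_pcs
  if (length(use_pcs) == 0) {
    warn("No jackstraw-significant PCs; step 4 contributes no calls.")
    pc_calls <- tibble(gene_id = character(), source = character(),
                       pc = integer(), loading = numeric())
  } else {
    pc_calls <- pc_loading_genes(pca, pcs = use_pcs, top_n = top_n)
  }
  dels <- combine_dels(ttest_calls, pc_calls, mode = combine)
  z_del <- filter_genes(z, dels$genes)
  final <- final_domains(z_del, k_final, seed = derive_seed(seed, 2),
                         n_init = n_init)
  groups <- bic_skmeans(z_del, k_range = k_range,
                        seed = derive_seed(seed, 3), n_init = n_init)
  structure(list(hvg = hvg, zscores = z, preliminary = prelim,
                 ttest_calls = ttest_calls, pca = pca, jackstraw = js,
                 pc_calls = pc_calls, dels = dels, final = final,
                 groups = groups,
                 params = list(n_hvg = n_hvg, k_prelim = k_prelim,
                               p_thresh = p_thresh, fc_thresh = fc_thresh,
                               n_pcs = n_pcs, pcs = use_pcs, top_n = top_n,
                               combine = combine, k_final = k_final,
                               k_range = k_range, seed = seed,
                               n_init = n_init)),
            class = "spatial_del_fit")
}

#' @export
print.spatial_del_fit <- function(x, ...) {
  cat(sprintf(paste0("<spatial_del_fit> %d HVGs, %d preliminary domains, ",
                     "%d DELs, %d final domains, %d gene groups\n"),
              length(x$hvg), attr(x$preliminary, "K"), length(x$dels$genes),
              attr(x$final, "K"), x$groups$k_selected))
  invisible(x)
}

#' @rdname spatial_del_pipeline
#' @param x,object a `spatial_del_fit`.
#' @param ... unused.
#' @method tidy spatial_del_fit
#' @export
tidy.spatial_del_fit <- function(x, ...) {
  as_tibble(x$dels$calls)
}

#' @rdname spatial_del_pipeline
#' @method glance spatial_del_fit
#' @export
glance.spatial_del_fit <- function(x, ...) {
  tibble(n_hvg = length(x$hvg),
         k_prelim = attr(x$preliminary, "K"),
         n_ttest_genes = dplyr::n_distinct(x$ttest_calls$gene_id),
         n_pc_genes = dplyr::n_distinct(x$pc_calls$gene_id),
         n_dels = length(x$dels$genes),
         n_significant_pcs = length(x$jackstraw$significant_pcs),
         k_final = attr(x$final, "K"),
         k_groups = x$groups$k_selected)
}

#' @rdname spatial_del_pipeline
#' @method autoplot spatial_del_fit
#' @export
autoplot.spatial_del_fit <- function(object, ...) {
  autoplot(object$groups, ...)
}
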