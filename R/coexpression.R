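#' Soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power, the co-expression adjacency
#' `a_ij = |cor(g_i, g_j)|^beta` (or `((1 + cor)/2)^beta` for a signed
#' network) gives a connectivity `k_i = sum_j a_ij`.  The connectivities are
#' binned into `n_bins` logarithmic bins and the scale-free fit is the
#' squared Pearson correlation of log10(mean k per bin) versus
#' log10(frequency), requiring a negative slope.  The smallest power
#' reaching `r2_target` is returned; if none does, the power with maximal
#' fit, with a warning.
#'
#' @param expr log2-scale expression tibble (genes x samples).
#' @param powers candidate integer powers.
#' @param r2_target scale-free fit threshold (default 0.8).
#' @param signed use the signed adjacency transform.
#' @param n_bins connectivity bins for the fit.
#' @return A tibble row: beta, r2, signed; the full scan is in attribute
#'   `"scan"`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            signed = FALSE, n_bins = 10) {
  m <- expr_mat(expr)
  if (nrow(m) < 2) arg_error("Need >= 2 genes.")
  if (ncol(m) < 4) arg_error("Need >= 4 samples.")
  cc <- cor(t(m))
  scan <- purrr::map_dfr(powers, function(b) {
    a <- adjacency_from_cor(cc, b, signed)
    k <- colSums(a)
    tibble(beta = b, r2 = scale_free_fit(k, n_bins))
  })
  ok <- which(scan$r2 >= r2_target)
  if (length(ok) > 0) {
    pick <- ok[1]
  } else {
    warn(sprintf("No power reached scale-free fit R^2 >= %.2f; using max (R^2 = %.3f).",
                 r2_target, max(scan$r2, na.rm = TRUE)))
    pick <- which.max(scan$r2)
  }
  out <- tibble(beta = scan$beta[pick], r2 = scan$r2[pick], signed = signed)
  attr(out, "scan") <- scan
  out
}

## conventional fallback powers by sample size (doubled for signed
## networks), used when no scanned power reaches the scale-free target --
## e.g. on small planted-block networks whose degree distribution is not
## power-law at all
default_soft_power <- function(n_samples, signed) {
  base <- if (n_samples < 20) 9 else if (n_samples < 30) 8 else
    if (n_samples < 40) 7 else 6
  if (signed) 2 * base else base
}

adjacency_from_cor <- function(cc, beta, signed) {
  a <- if (signed) ((1 + cc) / 2) ^ beta else abs(cc) ^ beta
  diag(a) <- 0
  a
}

## R^2 of the log-log regression of binned connectivity frequency, signed to
## fail (0) when the slope is positive
scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < 3) return(NA_real_)
  breaks <- exp(seq(log(min(k)), log(max(k)), length.out = n_bins + 1))
  breaks[1] <- breaks[1] * (1 - 1e-9)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- log10(mean_k[keep]); y <- log10(freq[keep] / sum(freq[keep]))
  r <- cor(x, y)
  if (is.na(r) || r > 0) 0 else r ^ 2
}

#' Topological overlap matrix
#'
#' Transforms the soft-thresholded adjacency into the topological overlap
#' matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`, quantifying shared network neighborhoods.
#'
#' @param expr log2-scale expression tibble.
#' @param beta soft-thresholding power.
#' @param signed use the signed adjacency transform.
#' @return A `tom_matrix`: symmetric gene x gene matrix in \[0, 1\] with
#'   unit diagonal.
#' @export
compute_tom <- function(expr, beta, signed = FALSE) {
  m <- expr_mat(expr)
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d constant gene(s) before TOM.", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) arg_error("Need >= 2 non-constant genes.")
  a <- adjacency_from_cor(cor(t(m)), beta, signed)
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  structure(tom, class = c("tom_matrix", "matrix"))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a simplified tree cut: the dendrogram is cut at an adaptive
#' height (the midpoint of the largest gap among the upper merge heights,
#' overridable via `cut_height`), branches of size >= `min_size` become
#' modules and all other genes are left unassigned ("grey").  Modules whose
#' eigengenes have dissimilarity `1 - cor < merge_cut` are then merged
#' iteratively.
#'
#' @param expr log2-scale expression tibble (for eigengene-based merging).
#' @param tom a [compute_tom()] result.
#' @param min_size minimum module size (default 30).
#' @param merge_cut eigengene dissimilarity below which modules merge.
#' @param cut_height optional fixed dendrogram cut height in \[0, 1\].
#' @return Tibble gene_id, module ("M1", "M2", ... or "grey").
#' @export
detect_modules <- function(expr, tom, min_size = 30, merge_cut = 0.25,
                           cut_height = NULL) {
  genes <- rownames(tom)
  if (length(genes) < min_size) {
    warn("Fewer genes than `min_size`; zero modules.")
    return(tibble(gene_id = genes, module = "grey"))
  }
  hc <- hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) cut_height <- adaptive_cut_height(hc$height)
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0) {
    warn("No branch reaches `min_size`; zero modules.")
    return(tibble(gene_id = genes, module = "grey"))
  }
  module <- ifelse(cl %in% as.integer(keep),
                   paste0("M", match(cl, sort(as.integer(keep)))), "grey")
  out <- tibble(gene_id = genes, module = module)
  merge_similar_modules(expr, out, merge_cut)
}

## midpoint of the largest gap among merge heights in the upper half of the
## dendrogram; separates well-formed blocks from their much higher joins
adaptive_cut_height <- function(heights) {
  h <- sort(heights)
  upper <- h[h >= stats::median(h)]
  if (length(upper) < 2) return(max(h) * 0.99)
  gaps <- diff(upper)
  i <- which.max(gaps)
  (upper[i] + upper[i + 1]) / 2
}

merge_similar_modules <- function(expr, assignment, merge_cut) {
  repeat {
    mods <- setdiff(unique(assignment$module), "grey")
    if (length(mods) < 2) break
    eg <- vapply(mods, function(mm) {
      module_eigengene(expr, assignment$gene_id[assignment$module == mm])
    }, numeric(ncol(expr) - 1))
    diss <- 1 - cor(eg)
    diag(diss) <- Inf
    if (min(diss) >= merge_cut) break
    idx <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    a <- mods[min(idx)]; b <- mods[max(idx)]
    assignment$module[assignment$module == b] <- a
  }
  mods <- setdiff(unique(assignment$module), "grey")
  relabel <- setNames(paste0("M", seq_along(mods)), mods)
  assignment$module <- ifelse(assignment$module == "grey", "grey",
                              relabel[assignment$module])
  assignment
}

#' Module eigengene
#'
#' First principal component of the z-scored member-gene submatrix across
#' samples, unit-normalized and sign-fixed to correlate positively with the
#' average member profile.
#'
#' @param expr log2-scale expression tibble.
#' @param genes member gene ids.
#' @return Named per-sample numeric vector of unit Euclidean norm.
#' @export
module_eigengene <- function(expr, genes) {
  if (length(genes) == 0) arg_error("Module must be non-empty.")
  m <- expr_mat(filter_genes(expr, genes))
  sds <- apply(m, 1, sd)
  if (all(sds == 0)) {
    warn("Singular module submatrix; falling back to the average profile.")
    avg <- colMeans(m)
    nrm <- sqrt(sum(avg ^ 2))
    return(if (nrm > 0) avg / nrm else avg)
  }
  m <- m[sds > 0, , drop = FALSE]
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  sv <- svd(z)
  e <- sv$v[, 1]
  avg <- colMeans(z)
  if (sd(avg) > 0 && cor(e, avg) < 0) e <- -e
  setNames(e, colnames(m))
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each numeric sample
#' trait, with the two-sided Student-t p-value
#' `p = 2 P(T_{n-2} > |r| sqrt((n-2)/(1-r^2)))`.
#'
#' @param eigengenes named list of per-sample eigengene vectors (one per
#'   module), all aligned to the same samples.
#' @param traits named list (or data frame) of per-sample numeric trait
#'   vectors.
#' @return Tibble: module, trait, r, p (NA for constant traits).
#' @export
module_trait <- function(eigengenes, traits) {
  traits <- as.list(traits)
  purrr::map_dfr(names(eigengenes), function(mm) {
    e <- eigengenes[[mm]]
    purrr::map_dfr(names(traits), function(tr) {
      tv <- traits[[tr]]
      if (length(tv) != length(e)) arg_error("Trait length mismatch.")
      if (sd(tv) == 0 || sd(e) == 0) {
        return(tibble(module = mm, trait = tr, r = NA_real_, p = NA_real_))
      }
      n <- length(e)
      r <- cor(e, tv)
      p <- if (abs(r) >= 1) 0 else
        2 * pt(abs(r) * sqrt((n - 2) / (1 - r ^ 2)), n - 2,
               lower.tail = FALSE)
      tibble(module = mm, trait = tr, r = r, p = p)
    })
  })
}

#' Assign temporal categories to modules
#'
#' Labels each module by its eigengene's correlation with genotype and day:
#' a module is WT-flavored when `cor(E, genotype == "GKO") < -r_min` and
#' GKO-flavored when `> r_min`; within the flavored genotype's samples it is
#' Early when `cor(E, day) < -r_min`, Late when `> r_min`, and constant
#' otherwise.  Because a correlation on a flat eigengene is pure sampling
#' noise (null sd about `1/sqrt(n)` regardless of expression noise), Early
#' and Late additionally require the day correlation to be significant at
#' p < 0.05; non-significant trends count as constant.  Only the four
#' composite labels WT-Early, WT-Late, GKO-Early and GKO-constant are
#' reported; any other combination is "unassigned".
#'
#' @param eigengenes named list of per-sample eigengene vectors.
#' @param meta sample metadata with numeric `day` and `genotype`
#'   ("WT"/"GKO") aligned to the eigengene samples.
#' @param r_min correlation threshold (default 0.3).
#' @return Tibble: module, category, r_genotype, r_day.
#' @export
categorize_modules <- function(eigengenes, meta, r_min = 0.3) {
  if (!all(c("day", "genotype") %in% names(meta))) {
    arg_error("`meta` must provide `day` and `genotype`.")
  }
  gko <- as.numeric(meta$genotype == "GKO")
  purrr::map_dfr(names(eigengenes), function(mm) {
    e <- eigengenes[[mm]]
    rg <- if (sd(gko) == 0) NA_real_ else cor(e, gko)
    flavor <- if (!is.na(rg) && rg < -r_min) "WT" else
      if (!is.na(rg) && rg > r_min) "GKO" else NA_character_
    rd <- NA_real_
    rd_p <- NA_real_
    if (!is.na(flavor)) {
      idx <- which(meta$genotype == flavor)
      if (sd(meta$day[idx]) > 0 && sd(e[idx]) > 0) {
        rd <- cor(e[idx], meta$day[idx])
        nn <- length(idx)
        rd_p <- if (abs(rd) >= 1) 0 else
          2 * pt(abs(rd) * sqrt((nn - 2) / (1 - rd ^ 2)), nn - 2,
                 lower.tail = FALSE)
      }
    }
    ## an eigengene that is literally flat within its genotype is the
    ## archetypal "constant" module, not an unassignable one
    timing <- if (is.na(flavor)) NA_character_ else
      if (is.na(rd)) "constant" else
      if (rd < -r_min && rd_p < 0.05) "Early" else
      if (rd > r_min && rd_p < 0.05) "Late" else "constant"
    label <- if (is.na(flavor) || is.na(timing)) "unassigned" else
      paste(flavor, timing, sep = "-")
    if (!label %in% c("WT-Early", "WT-Late", "GKO-Early", "GKO-constant")) {
      label <- "unassigned"
    }
    tibble(module = mm, category = label, r_genotype = rg, r_day = rd)
  })
}

#' Co-expression pipeline: network, modules, eigengenes, categories
#'
#' Log2-transforms the expression table, picks the soft power, builds the
#' TOM, detects and merges modules, computes module eigengenes, correlates
#' them with the day and genotype traits, and assigns temporal categories.
#' The network is signed by default here (anticorrelated temporal programs
#' must not fuse); the individual functions default to unsigned.
#'
#' @param expr linear-scale expression tibble.
#' @param meta sample metadata with `day` and `genotype`.
#' @param beta soft power; `NULL` (default) to scan via [pick_soft_power()].
#' @param signed signed network (default TRUE for the pipeline).
#' @param min_size,merge_cut,cut_height see [detect_modules()].
#' @param r_min category threshold, see [categorize_modules()].
#' @return A `coexpr_fit` object; `tidy()` gives gene-module-category rows,
#'   `glance()` a one-row summary, `autoplot()` the module-trait heatmap.
#' @export
coexpression_pipeline <- function(expr, meta, beta = NULL, signed = TRUE,
                                  min_size = 30, merge_cut = 0.25,
                                  cut_height = NULL, r_min = 0.3) {
  lg <- to_log2(expr)
  power <- if (is.null(beta)) {
    pp <- suppressWarnings(pick_soft_power(lg, signed = signed))
    if (pp$r2 >= 0.8) pp$beta else default_soft_power(ncol(lg) - 1, signed)
  } else beta
  tom <- compute_tom(lg, beta = power, signed = signed)
  modules <- detect_modules(lg, tom, min_size = min_size,
                            merge_cut = merge_cut, cut_height = cut_height)
  mods <- setdiff(unique(modules$module), "grey")
  eigengenes <- lapply(setNames(mods, mods), function(mm) {
    module_eigengene(lg, modules$gene_id[modules$module == mm])
  })
  traits <- list(day = meta$day,
                 genotype_gko = as.numeric(meta$genotype == "GKO"))
  trait_cor <- if (length(mods) > 0) module_trait(eigengenes, traits) else
    tibble(module = character(), trait = character(), r = numeric(),
           p = numeric())
  categories <- if (length(mods) > 0) categorize_modules(eigengenes, meta,
                                                         r_min = r_min) else
    tibble(module = character(), category = character(),
           r_genotype = numeric(), r_day = numeric())
  structure(list(beta = power, signed = signed, tom = tom,
                 modules = modules, eigengenes = eigengenes,
                 trait_correlations = trait_cor, categories = categories,
                 meta = meta),
            class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, ...) {
  mods <- setdiff(unique(x$modules$module), "grey")
  cat(sprintf("<coexpr_fit> beta = %d (%s), %d modules, categories: %s\n",
              x$beta, if (x$signed) "signed" else "unsigned", length(mods),
              paste(sort(unique(x$categories$category)), collapse = ", ")))
  invisible(x)
}

#' @rdname coexpression_pipeline
#' @param x,object a `coexpr_fit`.
#' @param ... unused.
#' @method tidy coexpr_fit
#' @export
tidy.coexpr_fit <- function(x, ...) {
  dplyr::left_join(x$modules, x$categories, by = "module")
}

#' @rdname coexpression_pipeline
#' @method glance coexpr_fit
#' @export
glance.coexpr_fit <- function(x, ...) {
  mods <- setdiff(unique(x$modules$module), "grey")
  tibble(beta = x$beta, signed = x$signed, n_modules = length(mods),
         n_grey = sum(x$modules$module == "grey"),
         n_categories = dplyr::n_distinct(
           setdiff(x$categories$category, "unassigned")))
}

#' @rdname coexpression_pipeline
#' @method autoplot coexpr_fit
#' @export
autoplot.coexpr_fit <- function(object, ...) {
  ggplot2::ggplot(object$trait_correlations,
                  ggplot2::aes(x = .data$trait, y = .data$module,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1g)", .data$r, .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Module-trait correlations") +
    ggplot2::theme_minimal()
}
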