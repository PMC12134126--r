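#' Gene-group clustering by BIC-selected spherical K-means
#'
#' Clusters z-scored gene profiles with spherical K-means: rows are scaled to
#' unit Euclidean norm, genes are assigned to the centroid of maximal cosine
#' similarity, and each centroid is the normalized mean of its members
#' (Lloyd iterations until the assignment stabilizes, best of `n_init`
#' farthest-point-seeded restarts by residual sum of squares).  The number
#' of groups is chosen by minimizing a spherical-Gaussian BIC of the
#' residuals,
#' \deqn{BIC(K) = n d \ln(RSS / (n d)) + (K d + 1) \ln(n),}
#' with `n` genes, `d` samples, and `RSS` the total squared distance of the
#' unit profiles to their assigned centroids.  Ties pick the smaller K.
#'
#' @param expr z-score-scale expression tibble (DEL genes x samples).
#' @param k_range candidate numbers of groups (default 2:12; clipped to the
#'   gene count).
#' @param seed integer RNG seed.
#' @param n_init random restarts per K.
#' @param max_iter Lloyd iteration cap per restart.
#' @param spherical set `FALSE` for plain Euclidean K-means on the z-scored
#'   rows (no unit-norm scaling, mean centroids).
#' @return A `gene_groups` object: `assignment` tibble (gene_id, group),
#'   `k_selected`, `bic_curve` tibble (k, bic, rss, feasible), unit-norm
#'   `centroids` (groups x samples).
#' @export
bic_skmeans <- function(expr, k_range = 2:12, seed = 1, n_init = 50,
                        max_iter = 300, spherical = TRUE) {
  m <- expr_mat(expr)
  n <- nrow(m); d <- ncol(m)
  if (any(k_range < 1)) arg_error("`k_range` must contain positive K only.")
  k_range <- sort(unique(pmin(k_range, n)))
  x <- if (spherical) unit_rows(m) else m

  fits <- vector("list", length(k_range))
  withr::with_seed(seed, {
    for (i in seq_along(k_range)) {
      fits[[i]] <- skmeans_best(x, k_range[i], n_init, max_iter, spherical)
    }
  })
  rss <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$rss,
                numeric(1))
  feasible <- !is.na(rss)
  bic <- ifelse(feasible,
                n * d * log(pmax(rss, 1e-12) / (n * d)) +
                  (k_range * d + 1) * log(n),
                Inf)
  best <- which(bic == min(bic))[1]           # ties -> smaller K (sorted)
  fit <- fits[[best]]
  lab <- paste0("G", as.integer(factor(fit$assign, levels = unique(fit$assign))))
  centroids <- fit$centroids[unique(fit$assign), , drop = FALSE]
  rownames(centroids) <- unique(lab)
  structure(list(assignment = tibble(gene_id = rownames(m), group = lab),
                 k_selected = k_range[best],
                 bic_curve = tibble(k = k_range, bic = bic, rss = rss,
                                    feasible = feasible),
                 centroids = centroids, spherical = spherical, seed = seed),
            class = "gene_groups")
}

unit_rows <- function(m) {
  nr <- sqrt(rowSums(m ^ 2))
  if (any(nr == 0)) arg_error("Zero-norm gene row(s); z-score first.")
  m / nr
}

skmeans_best <- function(x, k, n_init, max_iter, spherical) {
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- skmeans_once(x, k, max_iter, spherical)
    if (is.null(fit)) next
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  best
}

## one farthest-point-seeded Lloyd run; returns NULL if an empty cluster
## persists after reseeding
skmeans_once <- function(x, k, max_iter, spherical, trace = FALSE) {
  n <- nrow(x)
  centroids <- x[kmeanspp_init(x, k), , drop = FALSE]
  assign_prev <- rep(0L, n)
  rss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dist2 <- point_centroid_dist2(x, centroids, spherical)
    assign <- max.col(-dist2, ties.method = "first")
    ## reseed any empty cluster to the point farthest from its centroid
    for (rep_try in 1:5) {
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty) == 0) break
      for (e in empty) {
        far <- which.max(dist2[cbind(seq_len(n), assign)])
        centroids[e, ] <- x[far, ]
      }
      dist2 <- point_centroid_dist2(x, centroids, spherical)
      assign <- max.col(-dist2, ties.method = "first")
    }
    if (length(setdiff(seq_len(k), unique(assign))) > 0) return(NULL)
    for (j in seq_len(k)) {
      mu <- colMeans(x[assign == j, , drop = FALSE])
      if (spherical) {
        nrm <- sqrt(sum(mu ^ 2))
        if (nrm > 0) mu <- mu / nrm
      }
      centroids[j, ] <- mu
    }
    if (trace) {
      d2 <- point_centroid_dist2(x, centroids, spherical)
      rss_trace <- c(rss_trace, sum(d2[cbind(seq_len(n), assign)]))
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  d2 <- point_centroid_dist2(x, centroids, spherical)
  rss <- sum(d2[cbind(seq_len(n), assign)])
  out <- list(assign = assign, centroids = centroids, rss = rss)
  if (trace) out$rss_trace <- rss_trace
  out
}

## squared distances; for unit rows and unit centroids 2 - 2 cos equals the
## squared Euclidean distance, so cosine assignment == min distance
point_centroid_dist2 <- function(x, centroids, spherical) {
  if (spherical) {
    2 - 2 * x %*% t(centroids)
  } else {
    outer(rowSums(x ^ 2), rep(1, nrow(centroids))) -
      2 * x %*% t(centroids) +
      outer(rep(1, nrow(x)), rowSums(centroids ^ 2))
  }
}

## k-means++-style seeding: first centre uniform, then proportional to the
## squared distance to the nearest chosen centre
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k == 1) return(centers)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE)) ^ 2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                       byrow = TRUE)) ^ 2))
  }
  centers
}

#' @export
print.gene_groups <- function(x, ...) {
  cat(sprintf("<gene_groups> %d genes in %d groups (BIC-selected from K in [%d, %d])\n",
              nrow(x$assignment), x$k_selected, min(x$bic_curve$k),
              max(x$bic_curve$k)))
  invisible(x)
}

#' @rdname bic_skmeans
#' @param x a `gene_groups` object.
#' @param ... unused.
#' @method tidy gene_groups
#' @export
tidy.gene_groups <- function(x, ...) as_tibble(x$assignment)

#' @rdname bic_skmeans
#' @method glance gene_groups
#' @export
glance.gene_groups <- function(x, ...) {
  tibble(k_selected = x$k_selected,
         bic_min = min(x$bic_curve$bic),
         n_genes = nrow(x$assignment),
         spherical = x$spherical)
}

#' @rdname bic_skmeans
#' @param object a `gene_groups` object.
#' @method autoplot gene_groups
#' @export
autoplot.gene_groups <- function(object, ...) {
  ggplot2::ggplot(object$bic_curve, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = "dashed") +
    ggplot2::labs(x = "Number of gene groups (K)", y = "BIC",
                  title = sprintf("BIC-SKmeans model selection (K = %d)",
                                  object$k_selected)) +
    ggplot2::theme_minimal()
}
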