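## Brute-force oracles, deliberately written as plain loops so they stay
## independent of the vectorized / GenomicRanges-backed implementations.

## expression tibble from a plain matrix
make_expr <- function(mat, scale = "linear") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  out <- tibble::as_tibble(mat, rownames = NA)
  out <- tibble::add_column(out, gene_id = rownames(mat), .before = 1)
  attr(out, "expr_scale") <- scale
  out
}

expr_to_mat <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  m
}

## Welch t-test + linear fold-change gate, one gene and one domain pair at a
## time, via stats::t.test
oracle_pairwise_del <- function(lin_mat, domains, p_thresh = 0.05,
                                fc_thresh = 1.5, eps = 1e-6) {
  doms <- sort(unique(domains))
  out <- list()
  for (a in seq_along(doms)) for (b in seq_along(doms)) {
    if (b <= a) next
    ia <- which(domains == doms[a]); ib <- which(domains == doms[b])
    for (g in rownames(lin_mat)) {
      xa <- log2(lin_mat[g, ia]); xb <- log2(lin_mat[g, ib])
      p <- if (sd(xa) == 0 && sd(xb) == 0) {
        if (mean(xa) == mean(xb)) 1 else 0
      } else {
        stats::t.test(xa, xb, var.equal = FALSE)$p.value
      }
      fc <- (mean(lin_mat[g, ia]) + eps) / (mean(lin_mat[g, ib]) + eps)
      fc <- max(fc, 1 / fc)
      if (!is.na(p) && p < p_thresh && fc >= fc_thresh) {
        out[[length(out) + 1]] <- data.frame(
          gene_id = g, domain_a = doms[a], domain_b = doms[b],
          p_value = p, fold_change = fc)
      }
    }
  }
  if (length(out) == 0) return(data.frame(gene_id = character()))
  do.call(rbind, out)
}

## nearest TSS by exhaustive scan
oracle_nearest <- function(ivs, genes) {
  res_gene <- character(nrow(ivs)); res_dist <- rep(NA_real_, nrow(ivs))
  for (i in seq_len(nrow(ivs))) {
    best_d <- Inf; best_g <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != ivs$chrom[i]) next
      tss <- genes$tss[j]
      d <- if (tss >= ivs$start[i] && tss < ivs$end[i]) 0 else
        min(abs(tss - ivs$start[i]), abs(tss - (ivs$end[i] - 1)))
      if (d < best_d || (d == best_d && !is.na(best_g) &&
                         genes$gene_id[j] < best_g)) {
        best_d <- d; best_g <- genes$gene_id[j]
      }
    }
    res_gene[i] <- best_g; res_dist[i] <- best_d
  }
  data.frame(nearest_gene = res_gene, distance = res_dist)
}

## half-open interval overlap by scan
oracle_overlaps <- function(a, b, min_bp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= min_bp)
  }, logical(1))
}

## all-pairs replicate consensus
oracle_consensus <- function(replicates, min_support = length(replicates)) {
  rep1 <- replicates[[1]]
  support <- rep(1L, nrow(rep1))
  for (rr in replicates[-1]) {
    support <- support + as.integer(oracle_overlaps(rep1, rr))
  }
  out <- rep1[support >= min_support, , drop = FALSE]
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

## element-wise TOM formula
oracle_tom <- function(lg_mat, beta, signed = FALSE) {
  cc <- cor(t(lg_mat))
  a <- if (signed) ((1 + cc) / 2) ^ beta else abs(cc) ^ beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

## exhaustive-enumeration spherical K-means + BIC over K in k_range
## (feasible for <= 9 genes, K <= 3); returns the global optimum
oracle_skmeans_bic <- function(z_mat, k_range = 1:3) {
  x <- z_mat / sqrt(rowSums(z_mat ^ 2))
  n <- nrow(x); d <- ncol(x)
  best_rss <- setNames(rep(Inf, length(k_range)), k_range)
  best_assign <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    for (r in seq_len(nrow(grid))) {
      assign <- grid[r, ]
      if (length(unique(assign)) != k) next
      rss <- 0
      for (j in seq_len(k)) {
        mem <- x[assign == j, , drop = FALSE]
        mu <- colMeans(mem)
        nrm <- sqrt(sum(mu ^ 2))
        if (nrm > 0) mu <- mu / nrm
        rss <- rss + sum(sweep(mem, 2, mu) ^ 2)
      }
      if (rss < best_rss[ki] - 1e-12) {
        best_rss[ki] <- rss
        best_assign[[ki]] <- assign
      }
    }
  }
  bic <- n * d * log(pmax(best_rss, 1e-12) / (n * d)) +
    (k_range * d + 1) * log(n)
  k_sel <- k_range[which.min(bic)]
  list(rss = best_rss, bic = unname(bic), k_selected = k_sel,
       assignment = best_assign[[which.min(bic)]])
}

## random interval tables over a toy genome
random_interval_tbl <- function(n, chroms = c("chr1", "chr2"), len = 1e5,
                                wmin = 50, wmax = 500) {
  w <- floor(runif(n, wmin, wmax))
  s <- floor(runif(n, 0, len - w))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE), start = s,
                 end = s + w)
}

random_gene_tbl <- function(n, chroms = c("chr1", "chr2"), len = 1e5) {
  s <- floor(runif(n, 0, len - 5000))
  str <- sample(c("+", "-"), n, replace = TRUE)
  g <- tibble::tibble(gene_id = sprintf("g%03d", sample.int(999, n)),
                      chrom = sample(chroms, n, replace = TRUE),
                      start = s, end = s + floor(runif(n, 1000, 5000)),
                      strand = str)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  g[!duplicated(g$gene_id), , drop = FALSE]
}

filter_genes_tbl <- function(expr, genes) {
  out <- expr[expr$gene_id %in% genes, , drop = FALSE]
  attr(out, "expr_scale") <- attr(expr, "expr_scale")
  out
}
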