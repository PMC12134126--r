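test_that("select_hvg ranks by variance with lexicographic tie-break", {
  m <- matrix(5, 4, 3, dimnames = list(c("b", "a", "d", "c"), NULL))
  m["b", ] <- c(1, 3, 5)   # variance 4, all others 0
  e <- make_expr(m, "log2")
  expect_equal(select_hvg(e, 1), "b")
  ## constant matrix: all tie at zero, lexicographic order
  e0 <- make_expr(matrix(2, 5, 3,
                         dimnames = list(c("e", "c", "a", "d", "b"), NULL)),
                  "log2")
  expect_equal(select_hvg(e0, 5), c("a", "b", "c", "d", "e"))
  expect_error(select_hvg(e, 0), class = "delatlas_argument_error")
  expect_error(select_hvg(e, 10), class = "delatlas_argument_error")
})

test_that("select_hvg matches a brute-force variance sort", {
  withr::local_seed(42)
  m <- matrix(rnorm(500), 50, 10)
  e <- make_expr(m, "log2")
  got <- select_hvg(e, 10)
  v <- apply(expr_to_mat(e), 1, var)
  expect_equal(got, names(sort(v, decreasing = TRUE))[1:10])
})

test_that("zscore_rows uses sample sd and drops constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(7, 7, 7))
  expect_warning(z <- zscore_rows(make_expr(m, "log2")), "constant")
  expect_equal(unname(expr_to_mat(z)["a", ]), c(-1, 0, 1))
  expect_false("b" %in% z$gene_id)
  withr::local_seed(1)
  zr <- zscore_rows(make_expr(matrix(rnorm(40), 4, 10), "log2"))
  zm <- expr_to_mat(zr)
  expect_equal(unname(rowMeans(zm)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(zm, 1, sd)), rep(1, 4), tolerance = 1e-10)
  expect_error(zscore_rows(make_expr(matrix(1, 3, 3), "log2")),
               class = "delatlas_empty_error")
})

test_that("preliminary domains recover identical-profile blocks exactly", {
  ## two sample blocks with identical within-block, opposite between-block
  ## gene profiles: zero correlation distance inside each block
  withr::local_seed(20)
  v <- rnorm(10, sd = 2)
  m <- cbind(matrix(v, 10, 6), matrix(-v, 10, 6)) +
    matrix(rnorm(120, sd = 0.01), 10, 12)
  colnames(m) <- sprintf("s%02d", 1:12)
  z <- zscore_rows(make_expr(m, "log2"))
  part <- preliminary_domains(z, 2)
  expect_equal(attr(part, "K"), 2)
  expect_equal(adjusted_rand_index(part$domain, rep(c("A", "B"), each = 6)), 1)
  ## K = n samples: every sample its own domain
  pn <- preliminary_domains(z, 12)
  expect_equal(dplyr::n_distinct(pn$domain), 12)
  expect_error(preliminary_domains(z, 13), class = "delatlas_argument_error")
})

test_that("preliminary domains match the planted End/Epi split at E6.5", {
  p <- embryo_preset("E6.5", noise_sigma = 1e-4, seed = 3)
  s <- simulate_embryo(p)
  lg <- to_log2(s$expr)
  z <- zscore_rows(lg)
  part <- preliminary_domains(z, 2)
  truth <- ifelse(s$meta$zipcode == "End", "End", "Epi")
  expect_equal(adjusted_rand_index(part$domain, truth), 1)
})

test_that("pairwise_del applies both gates and matches the Welch oracle", {
  withr::local_seed(7)
  ## 12 genes x 2 domains of 5 samples, moderate noise so both gates bite
  m <- 2 ^ matrix(rnorm(120, mean = 3, sd = 0.8), 12, 10)
  rownames(m) <- sprintf("g%02d", 1:12)
  colnames(m) <- sprintf("s%02d", 1:10)
  m[1, 1:5] <- m[1, 1:5] * 4          # clear call
  m[2, ] <- 8                          # identical -> FC 1, never called
  part <- tibble::tibble(sample_id = colnames(m),
                         domain = rep(c("A", "B"), each = 5))
  calls <- pairwise_del(make_expr(m), part)
  orc <- oracle_pairwise_del(m, rep(c("A", "B"), each = 5))
  expect_setequal(calls$gene_id, orc$gene_id)
  expect_true("g01" %in% calls$gene_id)
  expect_false("g02" %in% calls$gene_id)
  o <- orc[order(orc$gene_id), ]
  g <- calls[order(calls$gene_id), ]
  expect_equal(g$p_value, o$p_value, tolerance = 1e-12)
  expect_equal(g$fold_change, o$fold_change, tolerance = 1e-12)
})

test_that("pairwise_del pins the forced example and the FC gate", {
  m <- rbind(gA = c(4, 4, 4, 4, 1 + 1e-6, 1 - 1e-6, 1 + 2e-6, 1 - 2e-6))
  colnames(m) <- sprintf("s%d", 1:8)
  part <- tibble::tibble(sample_id = colnames(m),
                         domain = rep(c("A", "B"), each = 4))
  calls <- pairwise_del(make_expr(m), part, eps = 0)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$fold_change, 4, tolerance = 1e-5)
  ## FC 1.4 with minuscule p is still not called (fold-change gate)
  m2 <- rbind(gB = c(rep(1.4, 4), rep(1, 4)) *
                (1 + rnorm(8, sd = 1e-7)))
  colnames(m2) <- colnames(m)
  expect_equal(nrow(pairwise_del(make_expr(m2), part)), 0)
  ## domains of size 1 are rejected
  bad <- tibble::tibble(sample_id = colnames(m),
                        domain = c("A", rep("B", 7)))
  expect_error(pairwise_del(make_expr(m), bad),
               class = "delatlas_partition_error")
})

test_that("run_pca is orthonormal, ordered, and matches closed forms", {
  ## rank-1 matrix: all variance on PC1
  u <- c(1, -1, 2, 0.5); v <- c(1, 2, -1, 0.3, 2)
  m <- outer(u, v)
  rownames(m) <- letters[1:4]; colnames(m) <- sprintf("s%d", 1:5)
  pc <- run_pca(make_expr(m, "zscore"))
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-10)
  ## 2x2: hand-diagonalized eigenvectors of t(m) %*% m
  m2 <- rbind(a = c(2, 1), b = c(1, 2))
  colnames(m2) <- c("s1", "s2")
  pc2 <- run_pca(make_expr(m2, "zscore"))
  expect_equal(abs(unname(pc2$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  ## orthonormal loadings, sign convention
  withr::local_seed(3)
  mr <- matrix(rnorm(200), 20, 10)
  rownames(mr) <- sprintf("g%02d", 1:20); colnames(mr) <- sprintf("s%02d", 1:10)
  pcr <- run_pca(make_expr(mr, "zscore"))
  gram <- crossprod(pcr$loadings)
  expect_equal(unname(gram), diag(ncol(pcr$loadings)), tolerance = 1e-10)
  peaks <- apply(pcr$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(peaks > 0))
  expect_error(run_pca(make_expr(matrix(0, 3, 3), "zscore")),
               class = "delatlas_rank_error")
})

test_that("pc_loading_genes takes the signed tops and matches a sort oracle", {
  withr::local_seed(5)
  m <- matrix(rnorm(300), 30, 10)
  rownames(m) <- sprintf("g%02d", 1:30); colnames(m) <- sprintf("s%02d", 1:10)
  pca <- run_pca(zscore_rows(make_expr(m, "log2")))
  calls <- pc_loading_genes(pca, pcs = 1:3, top_n = 10)
  expect_equal(nrow(calls), 30)
  for (j in 1:3) {
    l <- sort(pca$loadings[, j])
    got <- calls$gene_id[calls$pc == j]
    expect_setequal(got, c(names(head(l, 5)), names(tail(l, 5))))
  }
  ## explicit toy: (0.9, -0.8, 0.1, ...) with top_n 2 -> genes 1 and 2
  fake <- structure(list(loadings = cbind(PC1 = c(g1 = 0.9, g2 = -0.8,
                                                  g3 = 0.1, g4 = 0.05))),
                    class = "del_pca")
  expect_setequal(pc_loading_genes(fake, 1, 2)$gene_id, c("g1", "g2"))
  expect_error(pc_loading_genes(fake, 2, 2), class = "delatlas_argument_error")
  expect_warning(pc_loading_genes(fake, 1, 10), "clipping")
})

test_that("combine_dels honours union and intersection", {
  tt <- tibble::tibble(gene_id = c("A", "B"), source = "ttest_fc")
  pc <- tibble::tibble(gene_id = c("B", "C"), source = "pc_loading")
  expect_equal(combine_dels(tt, pc, "union")$genes, c("A", "B", "C"))
  expect_equal(combine_dels(tt, pc, "intersection")$genes, "B")
  empty <- pc[0, ]
  expect_equal(combine_dels(tt, empty, "union")$genes, c("A", "B"))
  ds <- combine_dels(tt, pc, "union")
  expect_s3_class(tidy(ds), "tbl_df")
  expect_setequal(unique(tidy(ds)$gene_id), ds$genes)
})

test_that("final_domains recovers separated blocks deterministically", {
  withr::local_seed(2)
  m <- cbind(matrix(rnorm(60, 3), 10, 6), matrix(rnorm(60, -3), 10, 6))
  rownames(m) <- sprintf("g%02d", 1:10); colnames(m) <- sprintf("s%02d", 1:12)
  e <- make_expr(m, "zscore")
  p1 <- final_domains(e, 2, seed = 4)
  p2 <- final_domains(e, 2, seed = 4)
  expect_identical(p1, p2)
  expect_equal(adjusted_rand_index(p1$domain, rep(1:2, each = 6)), 1)
  expect_error(final_domains(e, 0), class = "delatlas_argument_error")
  expect_error(final_domains(e, 13), class = "delatlas_argument_error")
})

test_that("bic_skmeans handles K = 1 and recovers planted structure", {
  withr::local_seed(8)
  m <- matrix(rnorm(60, sd = 0.1), 6, 10) +
    rbind(matrix(2, 3, 10), matrix(-2, 3, 10))
  rownames(m) <- sprintf("g%d", 1:6); colnames(m) <- sprintf("s%02d", 1:10)
  z <- zscore_rows(make_expr(m, "log2"))
  g1 <- bic_skmeans(z, k_range = 1, seed = 1)
  expect_equal(g1$k_selected, 1)
  expect_equal(dplyr::n_distinct(g1$assignment$group), 1)
  ## orthogonal two-block profiles; enough samples that the per-cluster
  ## BIC penalty (d ln n) outweighs chance-level splits of tight clusters
  d <- 32
  p1 <- c(rep(3, d / 2), rep(0, d / 2))
  blocks <- rbind(matrix(p1, 8, d, byrow = TRUE),
                  matrix(rev(p1), 8, d, byrow = TRUE)) +
    matrix(rnorm(16 * d, sd = 0.3), 16, d)
  rownames(blocks) <- sprintf("g%02d", 1:16)
  colnames(blocks) <- sprintf("s%02d", seq_len(d))
  zb <- zscore_rows(make_expr(blocks, "log2"))
  fit <- bic_skmeans(zb, k_range = 1:3, seed = 2)
  expect_equal(fit$k_selected, 2)
  expect_equal(adjusted_rand_index(fit$assignment$group,
                                   rep(1:2, each = 8)), 1)
  ## centroids are unit vectors; determinism
  expect_equal(unname(sqrt(rowSums(fit$centroids ^ 2))),
               rep(1, 2), tolerance = 1e-10)
  expect_identical(fit$assignment,
                   bic_skmeans(zb, k_range = 1:4, seed = 2)$assignment)
})

test_that("spherical Lloyd iterations never increase the objective", {
  withr::local_seed(31)
  for (rep in 1:5) {
    m <- matrix(rnorm(30 * 8), 30, 8)
    x <- m / sqrt(rowSums(m ^ 2))
    fit <- delatlas:::skmeans_once(x, 3, max_iter = 50, spherical = TRUE,
                                   trace = TRUE)
    expect_true(all(diff(fit$rss_trace) <= 1e-10))
  }
})

test_that("BIC at the planted K beats nearby K on well-separated presets", {
  p <- embryo_preset("E7.5", seed = 13)
  s <- simulate_embryo(p)
  planted <- s$true_groups$gene_id[s$true_groups$group != "background"]
  z <- zscore_rows(filter_genes_tbl(to_log2(s$expr), planted))
  fit <- bic_skmeans(z, k_range = 3:9, seed = 13, n_init = 20)
  curve <- fit$bic_curve
  bic_at <- function(k) curve$bic[curve$k == k]
  expect_lte(bic_at(6), bic_at(3))
  expect_lte(bic_at(6), bic_at(9))
  expect_equal(fit$k_selected, 6)
})
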