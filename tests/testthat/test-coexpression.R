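test_that("TOM matches the element-wise formula and its invariants", {
  withr::local_seed(4)
  m <- matrix(rnorm(5 * 12), 5, 12)
  rownames(m) <- letters[1:5]; colnames(m) <- sprintf("s%02d", 1:12)
  tom <- compute_tom(make_expr(m, "log2"), beta = 6)
  orc <- oracle_tom(m, beta = 6)
  expect_equal(unclass(tom), orc, tolerance = 1e-12)
  expect_equal(unclass(tom), t(unclass(tom)))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 5))
})

test_that("TOM of an isolated perfectly correlated pair is 1", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  colnames(m) <- sprintf("s%d", 1:4)
  tom <- compute_tom(make_expr(m, "log2"), beta = 1)
  expect_equal(tom["a", "b"], 1)
  ## constant rows are dropped with a warning
  m2 <- rbind(m, c0 = c(5, 5, 5, 5))
  expect_warning(t2 <- compute_tom(make_expr(m2, "log2"), beta = 1),
                 "constant")
  expect_equal(nrow(t2), 2)
})

test_that("soft power scan matches a direct recomputation", {
  withr::local_seed(6)
  m <- matrix(rnorm(10 * 12), 10, 12)
  m[1:5, ] <- m[1:5, ] + rep(rnorm(12, sd = 2), each = 5)
  rownames(m) <- sprintf("g%02d", 1:10); colnames(m) <- sprintf("s%02d", 1:12)
  e <- make_expr(m, "log2")
  pp <- suppressWarnings(pick_soft_power(e, powers = 1:6, r2_target = 0.2))
  scan <- attr(pp, "scan")
  ## recompute the fit for each power independently
  cc <- cor(t(m))
  for (i in seq_len(nrow(scan))) {
    a <- abs(cc) ^ scan$beta[i]; diag(a) <- 0
    k <- colSums(a)
    expect_equal(scan$r2[i], delatlas:::scale_free_fit(k, 10),
                 tolerance = 1e-12)
  }
  ## r2_target = 0 accepts the first power
  p0 <- suppressWarnings(pick_soft_power(e, powers = 1:6, r2_target = 0))
  expect_equal(p0$beta, 1)
})

test_that("module detection recovers planted blocks and respects min_size", {
  withr::local_seed(11)
  prof <- diag(4)[rep(1:4, each = 35), ]
  m <- prof[, rep(1:4, each = 3)] * 4 + matrix(rnorm(140 * 12, sd = 0.1),
                                               140, 12)
  rownames(m) <- sprintf("g%03d", 1:140); colnames(m) <- sprintf("s%02d", 1:12)
  e <- make_expr(m, "log2")
  tom <- compute_tom(e, beta = 12, signed = TRUE)
  mod <- detect_modules(e, tom, min_size = 30)
  mods <- setdiff(unique(mod$module), "grey")
  expect_equal(length(mods), 4)
  expect_equal(adjusted_rand_index(mod$module, rep(1:4, each = 35)), 1)
  ## fewer genes than min_size: zero modules
  small <- make_expr(matrix(rnorm(20 * 6), 20, 6), "log2")
  tom_s <- compute_tom(small, beta = 2)
  expect_warning(ms <- detect_modules(small, tom_s, min_size = 30))
  expect_true(all(ms$module == "grey"))
})

test_that("highly correlated modules are merged at the eigengene cut", {
  withr::local_seed(12)
  shared <- rnorm(10, sd = 2)
  m <- rbind(matrix(rep(shared, each = 35), 35, 10) ,
             matrix(rep(shared + rnorm(10, sd = 0.4), each = 35), 35, 10)) +
    matrix(rnorm(700, sd = 0.2), 70, 10)
  rownames(m) <- sprintf("g%03d", 1:70); colnames(m) <- sprintf("s%02d", 1:10)
  e <- make_expr(m, "log2")
  tom <- compute_tom(e, beta = 12, signed = TRUE)
  mod <- detect_modules(e, tom, min_size = 30, merge_cut = 0.25,
                        cut_height = 0.2)
  ## the two planted halves have eigengene correlation ~0.95 -> one module
  expect_equal(length(setdiff(unique(mod$module), "grey")), 1)
})

test_that("module eigengene matches a small PCA and its sign convention", {
  ## identical member genes: eigengene proportional to the shared profile
  prof <- c(1, 3, 2, 5, 4, 6)
  m <- rbind(a = prof, b = prof, c = prof)
  colnames(m) <- sprintf("s%d", 1:6)
  e <- make_expr(m, "log2")
  eg <- module_eigengene(e, c("a", "b", "c"))
  expect_equal(abs(cor(eg, prof)), 1, tolerance = 1e-10)
  expect_gte(cor(eg, prof), 0)
  expect_equal(sum(eg ^ 2), 1, tolerance = 1e-10)
  ## 3-gene toy equals the svd-computed first PC
  withr::local_seed(13)
  m3 <- matrix(rnorm(18), 3, 6,
               dimnames = list(c("x", "y", "z"), sprintf("s%d", 1:6)))
  e3 <- make_expr(m3, "log2")
  z <- t(scale(t(m3)))
  sv <- svd(z)
  ref <- sv$v[, 1]
  if (cor(ref, colMeans(z)) < 0) ref <- -ref
  expect_equal(unname(module_eigengene(e3, c("x", "y", "z"))), ref,
               tolerance = 1e-10)
  ## permuting member order leaves the eigengene unchanged
  expect_equal(module_eigengene(e3, c("z", "x", "y")),
               module_eigengene(e3, c("x", "y", "z")), tolerance = 1e-10)
})

test_that("module-trait correlation equals the textbook formula", {
  eg <- list(M1 = c(1, 2, 3, 4) / sqrt(30))
  tr <- module_trait(eg, list(t1 = c(2, 4, 6, 8)))
  expect_equal(tr$r, 1)
  withr::local_seed(14)
  e <- rnorm(10); v <- rnorm(10)
  got <- module_trait(list(M = e), list(t = v))
  r <- cor(e, v)
  p <- 2 * pt(abs(r) * sqrt(8 / (1 - r ^ 2)), 8, lower.tail = FALSE)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, p, tolerance = 1e-12)
  expect_equal(got$p, cor.test(e, v)$p.value, tolerance = 1e-10)
  ## constant trait -> missing
  cn <- module_trait(list(M = e), list(t = rep(1, 10)))
  expect_true(is.na(cn$r) && is.na(cn$p))
})

test_that("category rule pins the forced cases", {
  meta <- tibble::tibble(day = rep(0:7, 2),
                         genotype = rep(c("WT", "GKO"), each = 8))
  gko_flat <- c(rep(-1, 8), rep(1, 8)) / 4
  cats <- categorize_modules(list(M = gko_flat), meta)
  expect_equal(cats$category, "GKO-constant")
  ## r_min = 1 assigns nothing
  expect_equal(categorize_modules(list(M = gko_flat), meta, r_min = 1)$category,
               "unassigned")
  wt_late <- c(scale(0:7)[, 1], rep(-1, 8)) / 4
  expect_equal(categorize_modules(list(M = wt_late), meta)$category,
               "WT-Late")
})

test_that("coexpression pipeline recovers the four planted programs", {
  tc <- simulate_timecourse(timecourse_preset(seed = 21))
  fit <- suppressWarnings(coexpression_pipeline(tc$expr, tc$meta))
  td <- tidy(fit)
  truth <- tc$true_programs$program[match(td$gene_id,
                                          tc$true_programs$gene_id)]
  planted <- truth != "background"
  ## modules reproduce the planted partition
  expect_gte(adjusted_rand_index(td$module[planted], truth[planted]), 0.95)
  ## each planted program maps onto its own category
  hit <- vapply(unique(truth[planted]), function(pr) {
    lab <- td$category[planted][truth[planted] == pr]
    mean(lab == pr) > 0.5
  }, logical(1))
  expect_gte(sum(hit), 3)
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})
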