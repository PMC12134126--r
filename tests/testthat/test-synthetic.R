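test_that("embryo simulation is seed-deterministic and conserves gene counts", {
  p <- embryo_preset("E6.5", n_genes_per_group = 5, n_background_genes = 20,
                     seed = 11)
  s1 <- simulate_embryo(p)
  s2 <- simulate_embryo(p)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$true_groups, s2$true_groups)
  expect_equal(nrow(s1$expr), 3 * 5 + 20)
  expect_setequal(s1$true_groups$gene_id, s1$expr$gene_id)
  ## truth tables partition the genes exactly
  expect_equal(anyDuplicated(s1$true_groups$gene_id), 0)
  expect_true(all(s1$expr[-1] >= 0))
})

test_that("stage presets plant the printed numbers of gene groups", {
  n_groups <- function(st) length(embryo_preset(st)$groups)
  expect_equal(n_groups("E6.5"), 3)
  expect_equal(n_groups("E7.0"), 5)  # 3 carried + 2 mesoderm-specific
  expect_equal(n_groups("E7.5"), 6)
  meso <- embryo_preset("E7.0")$groups[4:5]
  expect_true(all(vapply(meso, function(g) "Mes" %in% g$on_zipcodes,
                         logical(1))))
})

test_that("noise-free group effect is analytically forced", {
  ## one group, effect 2 log2 on PS, no gradient, no noise -> linear ratio 4
  p <- embryo_preset("E7.5", groups = list(
    group_spec("G1", 6, "PS", effect_log2 = 2)),
    n_background_genes = 2, noise_sigma = 0, seed = 1)
  s <- simulate_embryo(p)
  m <- expr_to_mat(s$expr)
  on <- s$meta$zipcode == "PS"
  ratios <- rowMeans(m[1:6, on]) / rowMeans(m[1:6, !on])
  expect_equal(unname(ratios), rep(4, 6))
})

test_that("planted effects calibrate within three standard errors", {
  p <- embryo_preset("E7.5", seed = 5)
  s <- simulate_embryo(p)
  lm2 <- log2(expr_to_mat(s$expr))
  for (grp in p$groups) {
    if (grp$gradient != 0) next   # gradient scales the expectation
    ids <- sprintf("%s.%03d", grp$group_id, seq_len(grp$n_genes))
    on <- s$meta$zipcode %in% grp$on_zipcodes
    diffs <- rowMeans(lm2[ids, on, drop = FALSE]) -
      rowMeans(lm2[ids, !on, drop = FALSE])
    se <- p$noise_sigma * sqrt(1 / sum(on) + 1 / sum(!on))
    expect_lt(abs(mean(diffs) - grp$effect_log2),
              3 * se / sqrt(grp$n_genes) + 3 * se)
  }
})

test_that("invalid embryo configurations error", {
  expect_error(embryo_preset("E6.5", groups = list(), n_background_genes = 0),
               class = "delatlas_config_error")
  expect_error(group_spec("G1", 0, "PS", 2), class = "delatlas_config_error")
  expect_error(group_spec("G1", 5, "PS", -1), class = "delatlas_config_error")
  expect_error(embryo_preset("E6.5", groups = list(
    group_spec("G1", 5, "PS", 2))), class = "delatlas_config_error")
})

test_that("timecourse programs co-vary within more than between", {
  tc <- simulate_timecourse(timecourse_preset(n_genes_per_program = 10,
                                              n_background_genes = 0,
                                              seed = 3))
  m <- log2(expr_to_mat(tc$expr))
  prog <- tc$true_programs$program
  cc <- cor(t(m))
  within <- c(); between <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (prog[i] == prog[j]) within <- c(within, cc[i, j]) else
      between <- c(between, cc[i, j])
  }
  expect_gt(mean(within), mean(between))
  ## WT-Late specifically
  wl <- which(prog == "WT-Late")
  expect_gt(mean(cc[wl, wl][upper.tri(cc[wl, wl])]),
            mean(cc[wl, -wl]))
})

test_that("noise-free timecourse programs correlate perfectly", {
  tc <- simulate_timecourse(timecourse_preset(n_genes_per_program = 4,
                                              n_background_genes = 0,
                                              noise_sigma = 0, seed = 1))
  m <- log2(expr_to_mat(tc$expr))
  wl <- grep("WTLate", rownames(m))
  cc <- cor(t(m[wl, ]))
  expect_equal(unname(cc), matrix(1, length(wl), length(wl)))
})

test_that("timecourse is seed-deterministic and validates inputs", {
  pr <- timecourse_preset(seed = 9)
  expect_identical(simulate_timecourse(pr)$expr, simulate_timecourse(pr)$expr)
  expect_error(timecourse_preset(days = 3), class = "delatlas_config_error")
})

test_that("fixture truth equals the brute-force nearest scan", {
  fx <- simulate_fixtures(fixture_spec(n_genes = 10, n_shared_intervals = 10,
                                       seed = 2))
  tr <- fx$truth$nearest
  o <- oracle_nearest(tr, fx$genes)
  expect_equal(tr$nearest_gene, o$nearest_gene)
  expect_equal(tr$distance, o$distance)
})

test_that("single-gene overlap fixture pins distance zero", {
  genes <- tibble::tibble(gene_id = "geneA", chrom = "chr1", start = 100,
                          end = 2000, strand = "+", tss = 100)
  iv <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  o <- oracle_nearest(iv, genes)
  res <- assign_nearest_gene(iv, genes)
  expect_equal(res$nearest_gene, "geneA")
  expect_equal(res$distance, 0)
  expect_equal(o$nearest_gene, "geneA")
})

test_that("fixtures are file-deterministic and bounds-checked", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sp <- fixture_spec(seed = 4)
  simulate_fixtures(sp, dir = d1)
  simulate_fixtures(sp, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(fixture_spec(genes = tibble::tibble(
    gene_id = "bad", chrom = "chr1", start = 0, end = 2e6, strand = "+")),
    class = "delatlas_config_error")
})
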