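#' Interval/peak/DEG fixture specification
#'
#' States a small artificial genome with gene models, per-replicate 4C-style
#' interaction intervals around a declared viewpoint, a differential
#' expression table, and H3K27ac/H3K4me3 peak sets — all with planted ground
#' truth so the screening and classification stages can be tested end to end.
#'
#' @param genome tibble with columns chrom, length.
#' @param n_genes genes placed uniformly across the genome (two exons each).
#' @param genes optional tibble of custom gene models (gene_id, chrom, start,
#'   end, strand); validated against the genome bounds.
#' @param n_replicates number of 4C replicates.
#' @param n_shared_intervals consensus interaction intervals present
#'   (jittered) in every replicate.
#' @param n_extra_intervals replicate-specific intervals.
#' @param viewpoint list(chrom, start, end); default mid of the last
#'   chromosome.
#' @param n_deg_up,n_deg_down planted significant DEGs among the consensus
#'   target genes.
#' @param n_k27_regions H3K27ac-increased regions; about half receive an
#'   overlapping H3K4me3 peak.
#' @param seed integer RNG seed.
#' @return A `fixture_spec` list; pass to [simulate_fixtures()].
#' @export
fixture_spec <- function(genome = tibble(chrom = c("chr1", "chr2", "chr7"),
                                         length = c(1e6, 1e6, 1e6)),
                         n_genes = 40, genes = NULL, n_replicates = 3,
                         n_shared_intervals = 30, n_extra_intervals = 8,
                         viewpoint = NULL, n_deg_up = 5, n_deg_down = 3,
                         n_k27_regions = 40, seed = 1) {
  if (nrow(genome) == 0) config_error("Genome must declare >= 1 chromosome.")
  if (!is.null(genes)) {
    len <- setNames(genome$length, genome$chrom)
    bad <- is.na(len[genes$chrom]) | genes$start < 0 |
      genes$end > len[genes$chrom] | genes$start >= genes$end
    if (any(bad)) {
      config_error(sprintf("Gene(s) outside chromosome bounds: %s",
                           paste(genes$gene_id[bad], collapse = ", ")))
    }
  }
  if (is.null(viewpoint)) {
    k <- nrow(genome)
    mid <- floor(genome$length[k] / 2)
    viewpoint <- list(chrom = genome$chrom[k], start = mid, end = mid + 5000)
  }
  structure(list(genome = genome, n_genes = n_genes, genes = genes,
                 n_replicates = n_replicates,
                 n_shared_intervals = n_shared_intervals,
                 n_extra_intervals = n_extra_intervals,
                 viewpoint = viewpoint, n_deg_up = n_deg_up,
                 n_deg_down = n_deg_down, n_k27_regions = n_k27_regions,
                 seed = seed),
            class = "fixture_spec")
}

## brute-force nearest-TSS rule; deliberately a plain loop so generator truth
## is independent of the vectorized implementation in the screen stage
brute_nearest_tss <- function(chrom, start, end, genes) {
  n <- length(chrom)
  out_gene <- character(n)
  out_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) { out_gene[i] <- NA_character_; next }
    d <- numeric(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      tss <- cand$tss[j]
      d[j] <- if (tss >= start[i] && tss < end[i]) 0 else
        min(abs(tss - start[i]), abs(tss - (end[i] - 1)))
    }
    ord <- order(d, cand$gene_id)
    out_gene[i] <- cand$gene_id[ord[1]]
    out_dist[i] <- d[ord[1]]
  }
  tibble(chrom = chrom, start = start, end = end,
         nearest_gene = out_gene, distance = out_dist)
}

overlaps_any <- function(s, e, starts, ends) {
  any(pmax(s, starts) < pmin(e, ends))
}

random_intervals <- function(n, genome, width_range) {
  chrom_idx <- sample.int(nrow(genome), n, replace = TRUE)
  width <- floor(runif(n, width_range[1], width_range[2]))
  start <- floor(runif(n, 0, genome$length[chrom_idx] - width))
  tibble(chrom = genome$chrom[chrom_idx], start = start,
         end = start + width)
}

#' Simulate interval, peak and DEG fixtures with planted truth
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, writes `genes.gff3`,
#'   `rep<k>.bed`, `k27_up.bed`, `k4me3.bed`, `deg.tsv` and truth tables as
#'   plain-text files.
#' @return A list with gene models (`genes`, incl. `exons`), per-replicate
#'   interval tibbles (`replicates`), `viewpoint`, `deg`, `k27_regions`,
#'   `k4_peaks`, and a `truth` list: `nearest` (per consensus interval),
#'   `candidates` (screen outcome), `k27_classes` (pos/neg + annotation).
#' @export
simulate_fixtures <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  genome <- spec$genome
  withr::with_seed(spec$seed, {
    ## gene models: uniform TSS positions, random strand, two exons
    if (is.null(spec$genes)) {
      n <- spec$n_genes
      chrom_idx <- sample.int(nrow(genome), n, replace = TRUE)
      width <- floor(runif(n, 2000, 10000))
      start <- floor(runif(n, 0, genome$length[chrom_idx] - width))
      genes <- tibble(gene_id = sprintf("gene%03d", seq_len(n)),
                      chrom = genome$chrom[chrom_idx],
                      start = start, end = start + width,
                      strand = sample(c("+", "-"), n, replace = TRUE))
    } else {
      genes <- as_tibble(spec$genes)
    }
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    ## two exons: first and last 30% of the span, intron between
    exon_len <- pmax(1, floor((genes$end - genes$start) * 0.3))
    exons <- dplyr::bind_rows(
      tibble(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$start, end = genes$start + exon_len),
      tibble(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$end - exon_len, end = genes$end))

    ## shared (consensus) intervals, jittered per replicate; jitter is small
    ## relative to width so >= 1 bp overlap is preserved
    shared <- random_intervals(spec$n_shared_intervals, genome, c(500, 2000))
    replicates <- lapply(seq_len(spec$n_replicates), function(r) {
      jit <- floor(runif(nrow(shared), -100, 100))
      core <- tibble(chrom = shared$chrom, start = shared$start + jit,
                     end = shared$end + jit)
      core$start <- pmax(core$start, 0)
      extra <- random_intervals(spec$n_extra_intervals, genome, c(500, 2000))
      out <- dplyr::bind_rows(core, extra)
      out$name <- sprintf("rep%d_iv%03d", r, seq_len(nrow(out)))
      dplyr::arrange(out, .data$chrom, .data$start, .data$end)
    })

    ## truth: consensus = replicate-1 intervals overlapped in all others
    ## (brute-force scan), then nearest TSS per consensus interval
    rep1 <- replicates[[1]]
    support <- vapply(seq_len(nrow(rep1)), function(i) {
      1L + sum(vapply(replicates[-1], function(rr) {
        rr <- rr[rr$chrom == rep1$chrom[i], , drop = FALSE]
        overlaps_any(rep1$start[i], rep1$end[i], rr$start, rr$end)
      }, logical(1)))
    }, integer(1))
    consensus_truth <- rep1[support == spec$n_replicates, , drop = FALSE]
    nearest_truth <- brute_nearest_tss(consensus_truth$chrom,
                                       consensus_truth$start,
                                       consensus_truth$end, genes)
    target_genes <- sort(unique(stats::na.omit(nearest_truth$nearest_gene)))

    ## DEG table: planted up/down among target genes, plus significant
    ## non-targets and null genes
    n_up <- min(spec$n_deg_up, length(target_genes))
    n_dn <- min(spec$n_deg_down, max(0, length(target_genes) - n_up))
    picked <- sample(target_genes, n_up + n_dn)
    up <- picked[seq_len(n_up)]
    dn <- picked[n_up + seq_len(n_dn)]
    rest <- setdiff(genes$gene_id, picked)
    ## significant decoys must not be interaction targets, or they would be
    ## genuine candidates and the planted truth would understate the screen
    non_target <- setdiff(rest, target_genes)
    off_sig <- sample(non_target, min(4, length(non_target)))
    null_genes <- setdiff(rest, off_sig)
    deg <- dplyr::bind_rows(
      tibble(gene_id = up, log2FC = runif(n_up, 1, 3),
             padj = runif(n_up, 0, 0.01)),
      tibble(gene_id = dn, log2FC = -runif(n_dn, 1, 3),
             padj = runif(n_dn, 0, 0.01)),
      tibble(gene_id = off_sig, log2FC = runif(length(off_sig), 1, 2),
             padj = runif(length(off_sig), 0, 0.01)),
      tibble(gene_id = null_genes,
             log2FC = rnorm(length(null_genes), 0, 0.2),
             padj = runif(length(null_genes), 0.2, 1)))
    deg <- dplyr::arrange(deg, .data$gene_id)
    candidate_truth <- tibble(gene_id = sort(c(up, dn)),
                              direction = ifelse(sort(c(up, dn)) %in% up,
                                                 "up", "down"))

    ## H3K27ac-up regions; ~half receive an overlapping H3K4me3 peak
    k27 <- random_intervals(spec$n_k27_regions, genome, c(300, 1500))
    k27 <- dplyr::arrange(k27, .data$chrom, .data$start, .data$end)
    pos_idx <- sort(sample.int(nrow(k27), floor(nrow(k27) / 2)))
    k4 <- k27[pos_idx, , drop = FALSE]
    k4$start <- pmax(0, k4$start + floor(runif(nrow(k4), -200, 200)))
    k4$end <- k4$start + floor(runif(nrow(k4), 300, 800))
    ## jitter can break intended overlaps; the planted truth is recomputed by
    ## brute force below, so labels always reflect the emitted files
    k4 <- dplyr::bind_rows(k4, random_intervals(5, genome, c(300, 800)))
    k4 <- dplyr::arrange(k4, .data$chrom, .data$start, .data$end)
    k27_class <- vapply(seq_len(nrow(k27)), function(i) {
      kk <- k4[k4$chrom == k27$chrom[i], , drop = FALSE]
      if (overlaps_any(k27$start[i], k27$end[i], kk$start, kk$end))
        "H3K27ac_up_K4pos" else "H3K27ac_up_K4neg"
    }, character(1))
    ## brute-force midpoint annotation with the default promoter window
    mid <- k27$start + floor((k27$end - k27$start) / 2)
    annot <- vapply(seq_len(nrow(k27)), function(i) {
      g <- genes[genes$chrom == k27$chrom[i], , drop = FALSE]
      if (nrow(g) == 0) return("intergenic")
      prom <- ifelse(g$strand == "+",
                     mid[i] >= g$tss - 2000 & mid[i] <= g$tss + 500,
                     mid[i] >= g$tss - 500 & mid[i] <= g$tss + 2000)
      if (any(prom)) return("promoter")
      inside <- mid[i] >= g$start & mid[i] < g$end
      if (!any(inside)) return("intergenic")
      ex <- exons[exons$gene_id %in% g$gene_id[inside], , drop = FALSE]
      if (any(mid[i] >= ex$start & mid[i] < ex$end)) "exon" else "intron"
    }, character(1))
    k27_truth <- dplyr::bind_cols(k27, tibble(class_label = k27_class,
                                              annotation = annot))

    out <- list(genes = genes, exons = exons, replicates = replicates,
                viewpoint = spec$viewpoint, deg = deg,
                k27_regions = k27, k4_peaks = k4,
                truth = list(consensus = consensus_truth,
                             nearest = nearest_truth,
                             candidates = candidate_truth,
                             k27_classes = k27_truth))
  })
  if (!is.null(dir)) write_fixture_bundle(out, dir)
  out
}

write_fixture_bundle <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gff_genes(fx$genes, file.path(dir, "genes.gff3"))
  for (r in seq_along(fx$replicates)) {
    write_bed(fx$replicates[[r]], file.path(dir, sprintf("rep%d.bed", r)))
  }
  write_bed(fx$k27_regions, file.path(dir, "k27_up.bed"))
  write_bed(fx$k4_peaks, file.path(dir, "k4me3.bed"))
  readr::write_tsv(fx$deg, file.path(dir, "deg.tsv"))
  readr::write_tsv(fx$truth$nearest, file.path(dir, "truth_nearest.tsv"))
  readr::write_tsv(fx$truth$candidates, file.path(dir, "truth_candidates.tsv"))
  readr::write_tsv(fx$truth$k27_classes, file.path(dir, "truth_k27_classes.tsv"))
  invisible(dir)
}
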