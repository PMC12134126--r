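#' Interval tables and GRanges conversion
#'
#' Genomic intervals travel as tibbles with columns chrom, start, end
#' (0-based, half-open) plus optional name/score/strand.  Conversion to the
#' 1-based closed coordinates of `GenomicRanges` happens only inside the
#' overlap machinery.
#'
#' @param x interval tibble.
#' @keywords internal
as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

validate_intervals <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    arg_error("Interval table needs columns chrom, start, end.")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    arg_error("Intervals must satisfy 0 <= start < end.")
  }
  invisible(x)
}

sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Replicate consensus of interaction intervals
#'
#' Keeps the intervals of the first replicate that are overlapped (>= 1 bp,
#' half-open) by intervals of at least `min_support - 1` of the other
#' replicates; the default demands support in all replicates.
#'
#' @param replicates list of interval tibbles, one per replicate.
#' @param min_support replicates (including the first) that must support an
#'   interval; default `length(replicates)`.
#' @return Sorted tibble of consensus intervals with a `replicate_support`
#'   column.
#' @export
replicate_consensus <- function(replicates, min_support = length(replicates)) {
  if (length(replicates) == 0) arg_error("Need >= 1 replicate.")
  rep1 <- replicates[[1]]
  validate_intervals(rep1)
  gr1 <- as_granges(rep1)
  support <- rep(1L, nrow(rep1))
  for (rr in replicates[-1]) {
    hits <- GenomicRanges::countOverlaps(gr1, as_granges(rr), minoverlap = 1)
    support <- support + as.integer(hits > 0)
  }
  out <- rep1[support >= min_support, , drop = FALSE]
  out$replicate_support <- support[support >= min_support]
  sort_intervals(out)
}

#' Assign the nearest gene to each interaction interval
#'
#' For each interval, the nearest gene on the same chromosome by distance to
#' the gene TSS (0 when the TSS falls inside the half-open interval,
#' otherwise the base-pair distance to the closer interval edge), ties broken
#' by `gene_id` ascending.  Intervals on chromosomes without genes yield no
#' target; their count is reported via a message and the `"n_unassigned"`
#' attribute — this is how the number of interacting targets can exceed the
#' number of assigned genes.
#'
#' @param intervals interval tibble.
#' @param genes gene-model tibble (gene_id, chrom, strand, start, end, tss),
#'   as from [read_gff_genes()] or [simulate_fixtures()].
#' @param anchor "tss" (default) or "body" (distance to the gene span).
#' @return Tibble of interaction targets: interval columns plus
#'   nearest_gene, distance.
#' @export
assign_nearest_gene <- function(intervals, genes, anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  validate_intervals(intervals)
  if (nrow(genes) == 0) arg_error("Gene list must be non-empty.")
  out <- intervals
  out$nearest_gene <- NA_character_
  out$distance <- NA_real_
  for (cc in unique(intervals$chrom)) {
    g <- genes[genes$chrom == cc, , drop = FALSE]
    idx <- which(intervals$chrom == cc)
    if (nrow(g) == 0) next
    s <- intervals$start[idx]; e <- intervals$end[idx]
    if (anchor == "tss") {
      ## distance matrix intervals x genes to the TSS point
      d <- outer(s, g$tss, function(si, ti) abs(ti - si))
      d <- pmin(d, outer(e - 1, g$tss, function(ei, ti) abs(ti - ei)))
      inside <- outer(s, g$tss, `<=`) & outer(e, g$tss, `>`)
      d[inside] <- 0
    } else {
      ## distance between the closest covered bases; 0 when the spans overlap
      gene_left <- outer(s, g$end - 1, `-`)                  # gene upstream
      gene_right <- outer(e - 1, g$start, function(ei, gs) gs - ei)
      d <- pmax(gene_left, gene_right, 0)
    }
    ## per row: min distance, tie-break by gene_id ascending
    gene_rank <- order(g$gene_id)
    pick <- apply(d, 1, function(row) {
      cand <- which(row == min(row))
      cand[which.min(match(cand, gene_rank))]
    })
    out$nearest_gene[idx] <- g$gene_id[pick]
    out$distance[idx] <- d[cbind(seq_along(idx), pick)]
  }
  n_un <- sum(is.na(out$nearest_gene))
  if (n_un > 0) {
    inform(sprintf("%d interval(s) on chromosomes without genes were not assigned.",
                   n_un))
  }
  res <- out[!is.na(out$nearest_gene), , drop = FALSE]
  attr(res, "n_unassigned") <- n_un
  res
}

#' Parse a viewpoint string
#'
#' @param x "chrom:start-end" (0-based, half-open) or a list/tibble with
#'   chrom, start, end.
#' @return list(chrom, start, end).
#' @export
parse_viewpoint <- function(x) {
  if (is.character(x)) {
    mm <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
    if (length(mm) != 4) parse_error(sprintf("Malformed viewpoint '%s'.", x))
    x <- list(chrom = mm[2], start = as.numeric(mm[3]), end = as.numeric(mm[4]))
  }
  if (x$start >= x$end) parse_error("Viewpoint must satisfy start < end.")
  list(chrom = x$chrom, start = x$start, end = x$end)
}

#' Classify targets as intra- or inter-chromosomal
#'
#' @param targets tibble from [assign_nearest_gene()].
#' @param viewpoint viewpoint locus, see [parse_viewpoint()].
#' @return `targets` with a `chromosomal_class` column ("intra" iff on the
#'   viewpoint chromosome); class counts in attribute `"class_counts"`.
#' @export
classify_chromosomal <- function(targets, viewpoint) {
  vp <- parse_viewpoint(viewpoint)
  targets$chromosomal_class <- ifelse(targets$chrom == vp$chrom,
                                      "intra", "inter")
  counts <- table(factor(targets$chromosomal_class,
                         levels = c("intra", "inter")))
  attr(targets, "class_counts") <- as.list(as.integer(counts)) |>
    setNames(names(counts))
  targets
}

#' Screen interaction targets against differential expression
#'
#' Candidates are genes that are the nearest gene of at least one consensus
#' interaction target and show a significant expression change
#' (`padj < padj_thresh` and `|log2FC| >= lfc_thresh`).  Rows carry the
#' change direction and are ranked by descending |log2FC| (dense ranks,
#' ties broken by gene_id).
#'
#' @param targets tibble from [assign_nearest_gene()] (optionally already
#'   classified).
#' @param degs DEG tibble: gene_id, log2FC, padj.
#' @param padj_thresh adjusted-p threshold (default 0.05).
#' @param lfc_thresh |log2FC| threshold (default 0.585, i.e. 1.5-fold).
#' @return Candidate tibble: gene_id, direction, log2FC, padj, distance,
#'   (chromosomal_class if present), rank.
#' @export
screen_candidates <- function(targets, degs, padj_thresh = 0.05,
                              lfc_thresh = 0.585) {
  keep_cols <- intersect(c("nearest_gene", "distance", "chromosomal_class"),
                         names(targets))
  per_gene <- targets[keep_cols] |>
    dplyr::rename(gene_id = "nearest_gene") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(distance = min(.data$distance),
                     dplyr::across(dplyr::any_of("chromosomal_class"),
                                   ~ paste(sort(unique(.x)), collapse = "+")),
                     .groups = "drop")
  out <- dplyr::inner_join(per_gene, degs, by = "gene_id")
  out <- out[!is.na(out$padj) & out$padj < padj_thresh &
               abs(out$log2FC) >= lfc_thresh, , drop = FALSE]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$log2FC)), .data$gene_id)
  out$rank <- dplyr::dense_rank(dplyr::desc(abs(out$log2FC)))
  dplyr::select(out, "gene_id", "direction", "log2FC", "padj", "distance",
                dplyr::any_of("chromosomal_class"), "rank")
}

#' Full 4C-by-DEG candidate screen
#'
#' Replicate consensus, nearest-gene assignment, intra/inter classification
#' against the viewpoint, and intersection with the significant DEGs.
#'
#' @param replicates list of per-replicate interval tibbles.
#' @param genes gene-model tibble.
#' @param degs DEG tibble (gene_id, log2FC, padj).
#' @param viewpoint viewpoint locus, see [parse_viewpoint()].
#' @param min_support see [replicate_consensus()].
#' @param padj_thresh,lfc_thresh see [screen_candidates()].
#' @return A `multiomic_screen` object with consensus, targets, class
#'   counts and the candidate table; `tidy()` returns the candidates,
#'   `glance()` the headline counts.
#' @export
multiomic_screen <- function(replicates, genes, degs, viewpoint,
                             min_support = length(replicates),
                             padj_thresh = 0.05, lfc_thresh = 0.585) {
  consensus <- replicate_consensus(replicates, min_support)
  targets <- assign_nearest_gene(consensus, genes)
  targets <- classify_chromosomal(targets, viewpoint)
  candidates <- screen_candidates(targets, degs, padj_thresh, lfc_thresh)
  structure(list(consensus = consensus, targets = targets,
                 class_counts = attr(targets, "class_counts"),
                 n_unassigned = attr(targets, "n_unassigned"),
                 candidates = candidates, viewpoint = parse_viewpoint(viewpoint)),
            class = "multiomic_screen")
}

#' @export
print.multiomic_screen <- function(x, ...) {
  cat(sprintf(paste0("<multiomic_screen> %d consensus intervals -> %d targets ",
                     "(%d intra / %d inter), %d candidates (%d up / %d down)\n"),
              nrow(x$consensus), nrow(x$targets),
              x$class_counts$intra, x$class_counts$inter,
              nrow(x$candidates), sum(x$candidates$direction == "up"),
              sum(x$candidates$direction == "down")))
  invisible(x)
}

#' @rdname multiomic_screen
#' @param x a `multiomic_screen`.
#' @param ... unused.
#' @method tidy multiomic_screen
#' @export
tidy.multiomic_screen <- function(x, ...) as_tibble(x$candidates)

#' @rdname multiomic_screen
#' @method glance multiomic_screen
#' @export
glance.multiomic_screen <- function(x, ...) {
  tibble(n_consensus = nrow(x$consensus),
         n_targets = nrow(x$targets),
         n_target_genes = dplyr::n_distinct(x$targets$nearest_gene),
         n_unassigned = x$n_unassigned %||% 0L,
         n_intra = x$class_counts$intra,
         n_inter = x$class_counts$inter,
         n_candidates = nrow(x$candidates),
         n_up = sum(x$candidates$direction == "up"),
         n_down = sum(x$candidates$direction == "down"))
}
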