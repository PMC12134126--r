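#' Split H3K27ac-increased regions by H3K4me3 co-occurrence
#'
#' Labels each H3K27ac-up region `H3K27ac_up_K4pos` when it overlaps at
#' least one H3K4me3 peak by `min_overlap_bp` bases (half-open
#' coordinates), else `H3K27ac_up_K4neg`.  Every input region receives
#' exactly one label, so the two class counts always sum to the input count.
#'
#' @param up_regions interval tibble of H3K27ac-increased regions.
#' @param k4_peaks interval tibble of H3K4me3 peaks.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return `up_regions` with a `class_label` column.
#' @export
split_by_h3k4me3 <- function(up_regions, k4_peaks, min_overlap_bp = 1) {
  validate_intervals(up_regions)
  if (nrow(k4_peaks) == 0) {
    up_regions$class_label <- "H3K27ac_up_K4neg"
    return(up_regions)
  }
  hits <- GenomicRanges::countOverlaps(as_granges(up_regions),
                                       as_granges(k4_peaks),
                                       minoverlap = min_overlap_bp)
  up_regions$class_label <- ifelse(hits > 0, "H3K27ac_up_K4pos",
                                   "H3K27ac_up_K4neg")
  up_regions
}

#' Annotate regions genomically by their midpoint
#'
#' Assigns each region one annotation with precedence
#' promoter > exon > intron > intergenic, decided by the region midpoint:
#' promoter when the midpoint lies within the strand-aware window around any
#' TSS (default -2000/+500 bp), exon/intron when it falls inside a gene span
#' (exon if inside an exon, or always when no exon models are supplied),
#' else intergenic.  Also attaches the nearest gene by TSS distance.
#'
#' @param regions interval tibble (e.g. from [split_by_h3k4me3()]).
#' @param genes gene-model tibble (gene_id, chrom, start, end, strand, tss).
#' @param exons optional exon tibble (gene_id, chrom, start, end); without
#'   it, gene bodies count as exonic (whole-span fallback).
#' @param promoter_window c(upstream, downstream) in bp around the TSS,
#'   strand-aware; default c(-2000, 500).
#' @return `regions` with `annotation` and `nearest_gene` columns.
#' @export
annotate_regions <- function(regions, genes, exons = NULL,
                             promoter_window = c(-2000, 500)) {
  validate_intervals(regions)
  mid <- regions$start + floor((regions$end - regions$start) / 2)
  up <- promoter_window[1]; down <- promoter_window[2]
  annotation <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) { annotation[i] <- "intergenic"; next }
    prom_lo <- ifelse(g$strand == "+", g$tss + up, g$tss - down)
    prom_hi <- ifelse(g$strand == "+", g$tss + down, g$tss - up)
    if (any(mid[i] >= prom_lo & mid[i] <= prom_hi)) {
      annotation[i] <- "promoter"; next
    }
    inside <- mid[i] >= g$start & mid[i] < g$end
    if (!any(inside)) { annotation[i] <- "intergenic"; next }
    if (is.null(exons)) { annotation[i] <- "exon"; next }
    ex <- exons[exons$gene_id %in% g$gene_id[inside], , drop = FALSE]
    annotation[i] <- if (any(mid[i] >= ex$start & mid[i] < ex$end)) "exon"
      else "intron"
  }
  regions$annotation <- annotation
  nn <- assign_nearest_gene(regions, genes)
  regions$nearest_gene <- nn$nearest_gene[
    match(paste(regions$chrom, regions$start, regions$end),
          paste(nn$chrom, nn$start, nn$end))]
  regions
}

#' Summarize region classes and annotations
#'
#' Counts and within-class fractions per (class_label, annotation) pair,
#' i.e. the numbers behind the per-class annotation pie charts.
#'
#' @param classified tibble with `class_label` and `annotation` columns.
#' @return Tibble: class_label, annotation, n, fraction (summing to 1 within
#'   each class).
#' @export
class_summary <- function(classified) {
  if (nrow(classified) == 0) {
    return(tibble(class_label = character(), annotation = character(),
                  n = integer(), fraction = numeric()))
  }
  classified |>
    dplyr::count(.data$class_label, .data$annotation, name = "n") |>
    dplyr::group_by(.data$class_label) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
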