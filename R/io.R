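#' Read an expression table with sample metadata
#'
#' Reads a TSV whose first column is `gene_id` and whose remaining columns
#' are numeric sample values, together with a metadata TSV keyed by
#' `sample_id`.  Samples without metadata are an error; metadata rows
#' without matching samples produce a warning.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @return list(expr = linear-scale expression tibble, meta = tibble).
#' @export
read_expression <- function(expr_path, meta_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE, na = ".")
  names(expr)[1] <- "gene_id"
  dup <- expr$gene_id[duplicated(expr$gene_id)]
  if (length(dup) > 0) {
    parse_error(sprintf("Duplicated gene_id(s): %s",
                        paste(unique(dup), collapse = ", ")))
  }
  for (cn in setdiff(names(expr), "gene_id")) {
    if (!is.numeric(expr[[cn]])) {
      parse_error(sprintf("Non-numeric values in sample column '%s'.", cn))
    }
    if (anyNA(expr[[cn]])) {
      parse_error(sprintf("Missing values in sample column '%s'.", cn))
    }
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  if (!"sample_id" %in% names(meta)) {
    parse_error("Metadata must have a `sample_id` column.")
  }
  samples <- setdiff(names(expr), "gene_id")
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing) > 0) {
    parse_error(sprintf("Samples without metadata: %s",
                        paste(head(missing, 5), collapse = ", ")))
  }
  orphan <- setdiff(meta$sample_id, samples)
  if (length(orphan) > 0) {
    warn(sprintf("Metadata rows without samples: %s",
                 paste(head(orphan, 5), collapse = ", ")))
  }
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  list(expr = set_expr_scale(expr, "linear"), meta = meta)
}

#' Write an expression table and its sample metadata
#'
#' @param expr expression tibble.
#' @param meta metadata tibble.
#' @param expr_path,meta_path output TSV paths.
#' @export
write_expression <- function(expr, meta, expr_path, meta_path) {
  readr::write_tsv(expr, expr_path)
  readr::write_tsv(meta, meta_path)
  invisible(expr_path)
}

#' Read a BED file
#'
#' BED3-BED6, 0-based half-open.  Name and score are kept as character so a
#' read-write round trip of canonical sorted input is byte-identical.
#' Malformed lines raise a parse error naming the line number.
#'
#' @param path BED file path.
#' @return Sorted interval tibble: chrom, start, end (+ name, score, strand
#'   when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    parse_error(sprintf("BED line %d has fewer than 3 columns.",
                        which(nf < 3)[1]))
  }
  ncol <- min(max(nf), 6)
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    parse_error(sprintf("Malformed BED coordinates at line %d.", bad[1]))
  }
  out <- tibble(chrom = get(1), start = start, end = end)
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- get(5)
  if (ncol >= 6) out$strand <- get(6)
  sort_intervals(out)
}

#' Write a BED file
#'
#' @param x interval tibble (chrom, start, end, optionally name, score,
#'   strand).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  ## keep only a contiguous BED prefix, filling gaps with "."
  want <- c("chrom", "start", "end", "name", "score", "strand")
  last <- max(match(cols, want))
  m <- sapply(want[seq_len(last)], function(cn) {
    if (cn %in% names(x)) {
      v <- x[[cn]]
      if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else
        as.character(v)
    } else rep(".", nrow(x))
  })
  if (nrow(x) == 1) m <- matrix(m, nrow = 1)
  m[is.na(m)] <- "."
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read gene models from a GFF3 subset
#'
#' Keeps `gene` features only; converts the 1-based inclusive GFF
#' coordinates to the package's 0-based half-open convention and derives the
#' strand-aware TSS.  The gene id is taken from the `ID=` (or `gene_id=`)
#' attribute.
#'
#' @param path GFF3 file path.
#' @return Sorted gene-model tibble: gene_id, chrom, start, end, strand,
#'   tss.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad) > 0) {
    parse_error(sprintf("GFF line %d does not have 9 columns.", idx[bad[1]]))
  }
  type <- vapply(fields, `[[`, character(1), 3)
  g <- fields[type == "gene"]
  gidx <- idx[type == "gene"]
  if (length(g) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  tss = numeric()))
  }
  start1 <- suppressWarnings(as.numeric(vapply(g, `[[`, character(1), 4)))
  end1 <- suppressWarnings(as.numeric(vapply(g, `[[`, character(1), 5)))
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
  if (length(bad) > 0) {
    parse_error(sprintf("Malformed GFF coordinates at line %d.", gidx[bad[1]]))
  }
  attrs <- vapply(g, `[[`, character(1), 9)
  gene_id <- sub(".*(?:^|;)(?:ID|gene_id)=([^;]+).*", "\\1", attrs)
  out <- tibble(gene_id = gene_id,
                chrom = vapply(g, `[[`, character(1), 1),
                start = start1 - 1, end = end1,
                strand = vapply(g, `[[`, character(1), 7))
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1)
  sort_intervals(out)
}

#' Write gene models as a GFF3 subset
#'
#' @param genes gene-model tibble (0-based half-open internally; written
#'   1-based inclusive).
#' @param path output path.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tdelatlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start + 1),
                     as.integer(genes$end), genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}
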