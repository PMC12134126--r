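#' Planted gene-group specification
#'
#' Describes one planted group of spatially restricted genes for the embryo
#' simulator: how many genes, on which zipcodes they are elevated, by how
#' much (log2 units above baseline), and an optional linear gradient along
#' the anterior-posterior section axis.
#'
#' The `gradient` is the total fractional decay of the effect across the
#' section axis: `gradient = 0.8` means the effect multiplier falls linearly
#' from 1 at the most anterior section to 0.2 at the most posterior one;
#' a negative value decays in the opposite direction (posterior high), which
#' models genes peaking in the primitive streak and fading through the
#' mesoderm wings.
#'
#' @param group_id group label, e.g. "G1".
#' @param n_genes number of member genes (>= 1).
#' @param on_zipcodes zipcodes on which the group is elevated.
#' @param effect_log2 elevation above baseline in log2 units (> 0).
#' @param gradient total fractional decay along the section axis, in
#'   \[-1, 1\]; 0 means uniform.
#' @return A `group_spec` list.
#' @export
group_spec <- function(group_id, n_genes, on_zipcodes, effect_log2,
                       gradient = 0) {
  if (n_genes < 1) config_error("`n_genes` must be >= 1.")
  if (effect_log2 <= 0) config_error("`effect_log2` must be > 0.")
  if (abs(gradient) > 1) config_error("`gradient` must lie in [-1, 1].")
  structure(list(group_id = group_id, n_genes = n_genes,
                 on_zipcodes = on_zipcodes, effect_log2 = effect_log2,
                 gradient = gradient),
            class = "group_spec")
}

default_groups <- function(stage, n_genes, effect_log2) {
  g <- function(id, zips, grad = 0) {
    group_spec(id, n_genes, zips, effect_log2, grad)
  }
  switch(stage,
    ## early streak: two endoderm programs (anterior- and posterior-weighted)
    ## and one epiblast/ectoderm program
    "E6.5" = list(g("G1", "End", 1), g("G2", "End", -1), g("G3", "Ect")),
    ## mid streak: the E6.5 programs carried forward plus two new
    ## mesoderm-specific groups
    "E7.0" = list(g("G1", "End", 1), g("G2", "End", -1), g("G3", "Ect"),
                  g("G4", "Mes", 1), g("G5", "Mes", -1)),
    ## late streak: six groups across endoderm, ectoderm, mesoderm wings and
    ## a primitive-streak program decaying through the mesoderm
    "E7.5" = list(g("G1", "EA"), g("G2", "EP"), g("G3", c("A", "P")),
                  g("G4", "MA"), g("G5", "MP"),
                  g("G6", c("PS", "MA", "MP"), -0.7))
  )
}

default_layout <- function(stage, n_sections = NULL) {
  zips <- switch(stage,
    "E6.5" = c("End", "Ect"),
    "E7.0" = c("End", "Mes", "Ect"),
    "E7.5" = c("A", "P", "EA", "EP", "MA", "MP", "PS")
  )
  ## fewer zipcodes at earlier stages are compensated by deeper sectioning,
  ## mirroring the denser anterior-posterior sampling of small embryos
  if (is.null(n_sections)) {
    n_sections <- switch(stage, "E6.5" = 12, "E7.0" = 10, "E7.5" = 8)
  }
  tidyr::expand_grid(section_index = seq_len(n_sections), zipcode = zips)
}

#' Stage presets for the synthetic embryo
#'
#' Builds the stated simulation world for one gastrulation stage: a corn-plot
#' zipcode layout (sections along the anterior-posterior axis crossed with
#' germ-layer zipcodes) and the planted spatially restricted gene groups.
#' The presets mirror the biology of the three streak stages: 3 groups at
#' E6.5 (two endoderm, one epiblast/ectoderm), 5 at E7.0 (the three carried
#' forward plus two new mesoderm groups), and 6 at E7.5 including a
#' primitive-streak group that decays through the mesoderm wings.
#'
#' Defaults (group size 20, 16-fold elevation, log-normal noise with sd 0.15
#' on log2, 1600 unstructured background genes) are calibration choices that
#' make the planted structure clearly recoverable; see the methods vignette.
#' The preset also records `del_top_n`, the PC-loading harvest size matched
#' to the planted group size, for use as `top_n` when analysing this world.
#'
#' @param stage one of "E6.5", "E7.0", "E7.5".
#' @param n_sections sections along the anterior-posterior axis.
#' @param groups list of [group_spec()]; `NULL` for the stage default.
#' @param n_genes_per_group,effect_log2 defaults used when `groups` is NULL.
#' @param n_background_genes unstructured genes drawn iid around baseline.
#' @param noise_sigma Gaussian noise sd on the log2 scale (> 0).
#' @param baseline_log2 baseline log2 expression.
#' @param seed integer RNG seed.
#' @return An `embryo_preset` list; pass to [simulate_embryo()].
#' @export
embryo_preset <- function(stage = c("E7.5", "E6.5", "E7.0"),
                          n_sections = NULL, groups = NULL,
                          n_genes_per_group = 20, effect_log2 = 4,
                          n_background_genes = 1600, noise_sigma = 0.15,
                          baseline_log2 = 3, seed = 1) {
  stage <- match.arg(stage)
  layout <- default_layout(stage, n_sections)
  if (nrow(layout) == 0) config_error("Zipcode layout must be non-empty.")
  if (is.null(groups)) {
    groups <- default_groups(stage, n_genes_per_group, effect_log2)
  }
  if (length(groups) == 0 && n_background_genes == 0) {
    config_error("Preset contains zero genes.")
  }
  if (noise_sigma < 0) config_error("`noise_sigma` must be >= 0.")
  ids <- unlist(lapply(groups, `[[`, "group_id"))
  if (anyDuplicated(ids)) config_error("Group ids must be distinct.")
  for (grp in groups) {
    bad <- setdiff(grp$on_zipcodes, layout$zipcode)
    if (length(bad) > 0) {
      config_error(sprintf("Group %s targets zipcodes absent from the layout: %s",
                           grp$group_id, paste(bad, collapse = ", ")))
    }
  }
  sizes <- vapply(groups, `[[`, numeric(1), "n_genes")
  structure(list(stage = stage, zipcode_layout = layout, groups = groups,
                 n_background_genes = n_background_genes,
                 noise_sigma = noise_sigma, baseline_log2 = baseline_log2,
                 ## analysis parameter matched to the stated world: harvesting
                 ## more loading genes per PC than a planted group holds would
                 ## only dilute the DEL set with background
                 del_top_n = if (length(sizes)) 6 * max(sizes) else 120,
                 seed = seed),
            class = "embryo_preset")
}

## effect multiplier along the section axis for one group
gradient_multiplier <- function(gradient, section_index, n_sections) {
  if (n_sections == 1) return(rep(1, length(section_index)))
  frac <- (section_index - 1) / (n_sections - 1)
  if (gradient >= 0) 1 - gradient * frac else 1 + gradient * (1 - frac)
}

## zipcodes sharing the same set of covering groups form one spatial domain;
## this is the planted truth K-means is expected to recover
signature_domains <- function(layout, groups) {
  zips <- unique(layout$zipcode)
  sig <- vapply(zips, function(z) {
    paste(sort(vapply(groups,
                      function(g) if (z %in% g$on_zipcodes) g$group_id else "",
                      character(1))), collapse = "|")
  }, character(1))
  domain_of_zip <- setNames(paste0("Dom", as.integer(factor(sig, levels = unique(sig)))), zips)
  domain_of_zip
}

#' Simulate a corn-plot structured embryo transcriptome
#'
#' Draws a genes-by-samples FPKM-like expression matrix for one stage preset.
#' Each planted gene takes expected log2 value `baseline + effect * m(s)` on
#' its group's zipcodes (with `m(s)` the section gradient multiplier) and
#' `baseline` elsewhere; additive Gaussian noise on the log2 scale makes the
#' linear values log-normal.  Background genes are iid around baseline.
#'
#' @param preset an [embryo_preset()].
#' @return A list with elements
#'   \describe{
#'     \item{expr}{linear-scale expression tibble (gene_id + one column per sample).}
#'     \item{meta}{sample metadata tibble: sample_id, stage, section_index, zipcode.}
#'     \item{true_domains}{planted spatial-domain partition of the samples
#'       (zipcodes with identical group signatures share a domain).}
#'     \item{true_groups}{tibble gene_id, group ("background" for unplanted genes).}
#'   }
#' @export
simulate_embryo <- function(preset) {
  stopifnot(inherits(preset, "embryo_preset"))
  layout <- preset$zipcode_layout
  n_total <- sum(vapply(preset$groups, `[[`, numeric(1), "n_genes")) +
    preset$n_background_genes
  if (n_total == 0) config_error("Preset contains zero genes.")
  n_sections <- max(layout$section_index)
  sample_id <- sprintf("%s_S%02d_%s", preset$stage, layout$section_index,
                       layout$zipcode)
  meta <- tibble(sample_id = sample_id, stage = preset$stage,
                 section_index = layout$section_index,
                 zipcode = layout$zipcode)

  gene_rows <- list()
  truth <- list()
  for (grp in preset$groups) {
    ids <- sprintf("%s.%03d", grp$group_id, seq_len(grp$n_genes))
    mult <- gradient_multiplier(grp$gradient, layout$section_index, n_sections)
    on <- as.numeric(layout$zipcode %in% grp$on_zipcodes)
    mu <- preset$baseline_log2 + grp$effect_log2 * mult * on
    gene_rows[[grp$group_id]] <-
      matrix(mu, nrow = grp$n_genes, ncol = nrow(layout), byrow = TRUE,
             dimnames = list(ids, sample_id))
    truth[[grp$group_id]] <- tibble(gene_id = ids, group = grp$group_id)
  }
  if (preset$n_background_genes > 0) {
    ids <- sprintf("BG.%04d", seq_len(preset$n_background_genes))
    gene_rows[["background"]] <-
      matrix(preset$baseline_log2, nrow = length(ids), ncol = nrow(layout),
             dimnames = list(ids, sample_id))
    truth[["background"]] <- tibble(gene_id = ids, group = "background")
  }
  mu_mat <- do.call(rbind, gene_rows)
  log2_mat <- withr::with_seed(preset$seed, {
    mu_mat + matrix(rnorm(length(mu_mat), sd = preset$noise_sigma),
                    nrow = nrow(mu_mat))
  })
  dimnames(log2_mat) <- dimnames(mu_mat)

  dom <- signature_domains(layout, preset$groups)
  true_domains <- tibble(sample_id = sample_id,
                         domain = unname(dom[layout$zipcode]))
  list(expr = expr_tbl(2 ^ log2_mat, "linear"),
       meta = meta,
       true_domains = true_domains,
       true_groups = dplyr::bind_rows(truth))
}
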