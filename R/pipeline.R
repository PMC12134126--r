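#' Run the full analysis pipeline into an output directory
#'
#' Umbrella driver: executes the requested stages in dependency order on a
#' configuration list, writes every stage output as TSV into `out_dir`, and
#' finishes with a `manifest.json` recording the package version, the full
#' configuration and the MD5 checksum of every written file.  Outputs are
#' deterministic: the same configuration produces byte-identical files.
#'
#' Config keys (all optional except `seed`):
#' \describe{
#'   \item{seed}{integer base seed for all stages.}
#'   \item{stages}{subset of "simulate", "spatial", "coexpr", "screen",
#'     "epiclass" (default: all).}
#'   \item{simulate}{args for [embryo_preset()] (e.g. `stage`), plus the
#'     fixture/timecourse worlds are always emitted.}
#'   \item{spatial}{args for [spatial_del_pipeline()] (e.g. `top_n`,
#'     `k_range`).}
#'   \item{coexpr}{args for [coexpression_pipeline()].}
#'   \item{screen}{args for [multiomic_screen()] thresholds.}
#'   \item{epiclass}{args for [split_by_h3k4me3()]/[annotate_regions()].}
#' }
#' Unknown keys are rejected.
#'
#' @param config configuration list (see Details).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  allowed <- c("seed", "stages", "simulate", "spatial", "coexpr", "screen",
               "epiclass")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    config_error(sprintf("Unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "spatial", "coexpr", "screen",
                                 "epiclass")
  bad <- setdiff(stages, allowed[-(1:2)])
  if (length(bad) > 0) {
    config_error(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    written <<- c(written, path)
    path
  }

  preset <- do.call(embryo_preset,
                    c(config$simulate %||% list(), list(seed = seed)))
  sim <- simulate_embryo(preset)
  tc <- simulate_timecourse(timecourse_preset(seed = derive_seed(seed, 10)))
  fx <- simulate_fixtures(fixture_spec(seed = derive_seed(seed, 20)))

  if ("simulate" %in% stages) {
    emit(sim$expr, "embryo_expr.tsv")
    emit(sim$meta, "embryo_meta.tsv")
    emit(sim$true_domains, "embryo_true_domains.tsv")
    emit(sim$true_groups, "embryo_true_groups.tsv")
    emit(tc$expr, "timecourse_expr.tsv")
    emit(tc$meta, "timecourse_meta.tsv")
    emit(tc$true_programs, "timecourse_true_programs.tsv")
    fdir <- file.path(out_dir, "fixtures")
    write_fixture_bundle(fx, fdir)
    written <- c(written, list.files(fdir, full.names = TRUE))
  }
  if ("spatial" %in% stages) {
    fit <- do.call(spatial_del_pipeline,
                   c(list(expr = sim$expr, meta = sim$meta,
                          seed = derive_seed(seed, 30)),
                     config$spatial %||% list()))
    emit(tidy(fit), "del_calls.tsv")
    emit(fit$preliminary, "preliminary_domains.tsv")
    emit(fit$final, "final_domains.tsv")
    emit(tidy(fit$groups), "gene_groups.tsv")
    emit(fit$groups$bic_curve, "bic_curve.tsv")
    emit(glance(fit), "spatial_summary.tsv")
  }
  if ("coexpr" %in% stages) {
    cfit <- do.call(coexpression_pipeline,
                    c(list(expr = tc$expr, meta = tc$meta),
                      config$coexpr %||% list()))
    emit(tidy(cfit), "modules.tsv")
    eg <- purrr::imap_dfr(cfit$eigengenes, function(e, mm) {
      tibble(module = mm, sample_id = names(e), eigengene = unname(e))
    })
    emit(eg, "eigengenes.tsv")
    emit(cfit$trait_correlations, "module_trait.tsv")
  }
  if ("screen" %in% stages) {
    sfit <- do.call(multiomic_screen,
                    c(list(replicates = fx$replicates, genes = fx$genes,
                           degs = fx$deg, viewpoint = fx$viewpoint),
                      config$screen %||% list()))
    emit(sfit$targets, "interaction_targets.tsv")
    emit(tidy(sfit), "candidates.tsv")
    emit(glance(sfit), "screen_summary.tsv")
  }
  if ("epiclass" %in% stages) {
    cls <- do.call(split_by_h3k4me3,
                   c(list(up_regions = fx$k27_regions,
                          k4_peaks = fx$k4_peaks),
                     config$epiclass %||% list()))
    cls <- annotate_regions(cls, fx$genes, exons = fx$exons)
    emit(cls, "region_classes.tsv")
    emit(class_summary(cls), "region_class_summary.tsv")
  }

  manifest <- list(
    package = "delatlas",
    version = as.character(utils::packageVersion("delatlas")),
    seed = seed,
    stages = stages,
    config = config,
    checksums = as.list(tools::md5sum(sort(unique(written))))
  )
  names(manifest$checksums) <- basename(sort(unique(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
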