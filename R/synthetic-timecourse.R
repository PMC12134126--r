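#' Preset for the WT/GKO differentiation time course
#'
#' States the simulation world for the co-expression stage: two genotypes
#' (wild type and knockout) sampled over a differentiation time course, with
#' four planted temporal programs matching the categories the module-trait
#' analysis is expected to recover:
#' \describe{
#'   \item{WT-Early}{active only in WT, decaying linearly with day.}
#'   \item{WT-Late}{active only in WT, rising linearly with day.}
#'   \item{GKO-Early}{active only in GKO, decaying with day.}
#'   \item{GKO-constant}{active only in GKO, flat across days.}
#' }
#' Member genes share the program's latent day-by-genotype profile plus iid
#' Gaussian noise on the log2 scale.
#'
#' @param days ordered numeric time points (>= 2).
#' @param n_replicates samples per genotype and day.
#' @param n_genes_per_program member genes per program.
#' @param n_background_genes unstructured genes.
#' @param amplitude_log2 peak program elevation above baseline (log2 units).
#' @param noise_sigma Gaussian noise sd on log2 scale.
#' @param baseline_log2 baseline log2 expression.
#' @param seed integer RNG seed.
#' @return A `timecourse_preset` list; pass to [simulate_timecourse()].
#' @export
timecourse_preset <- function(days = 0:7, n_replicates = 2,
                              n_genes_per_program = 60,
                              n_background_genes = 80,
                              amplitude_log2 = 4, noise_sigma = 0.5,
                              baseline_log2 = 3, seed = 1) {
  if (length(days) < 2) config_error("At least 2 time points are required.")
  if (noise_sigma < 0) config_error("`noise_sigma` must be >= 0.")
  structure(list(genotypes = c("WT", "GKO"), days = days,
                 n_replicates = n_replicates,
                 programs = c("WT-Early", "WT-Late", "GKO-Early",
                              "GKO-constant"),
                 n_genes_per_program = n_genes_per_program,
                 n_background_genes = n_background_genes,
                 amplitude_log2 = amplitude_log2, noise_sigma = noise_sigma,
                 baseline_log2 = baseline_log2, seed = seed),
            class = "timecourse_preset")
}

## latent activity in [0, 1] of each program per (genotype, day); programs
## occupy day-activity windows (first/last ~third of the course) so that the
## four categories are pairwise distinguishable rather than collinear
program_activity <- function(program, genotype, day, days) {
  frac <- (day - min(days)) / diff(range(days))
  gt <- if (startsWith(program, "WT")) "WT" else "GKO"
  act <- switch(program,
    "WT-Early"     = as.numeric(frac <= 1 / 3),
    "WT-Late"      = as.numeric(frac >= 2 / 3),
    "GKO-Early"    = as.numeric(frac <= 1 / 3),
    "GKO-constant" = rep(1, length(day))
  )
  act * as.numeric(genotype == gt)
}

#' Simulate the WT/GKO time-course expression matrix
#'
#' @param preset a [timecourse_preset()].
#' @return A list with elements `expr` (linear-scale expression tibble),
#'   `meta` (sample_id, day, genotype, replicate), and `true_programs`
#'   (gene_id, program; "background" for unplanted genes).
#' @export
simulate_timecourse <- function(preset) {
  stopifnot(inherits(preset, "timecourse_preset"))
  grid <- tidyr::expand_grid(genotype = preset$genotypes, day = preset$days,
                             replicate = seq_len(preset$n_replicates))
  sample_id <- sprintf("%s_D%d_R%d", grid$genotype, grid$day, grid$replicate)
  meta <- tibble(sample_id = sample_id, day = grid$day,
                 genotype = grid$genotype, replicate = grid$replicate)

  rows <- list()
  truth <- list()
  for (prog in preset$programs) {
    ids <- sprintf("%s.%03d", gsub("-", "", prog),
                   seq_len(preset$n_genes_per_program))
    act <- program_activity(prog, grid$genotype, grid$day, preset$days)
    mu <- preset$baseline_log2 + preset$amplitude_log2 * act
    rows[[prog]] <- matrix(mu, nrow = length(ids), ncol = nrow(grid),
                           byrow = TRUE, dimnames = list(ids, sample_id))
    truth[[prog]] <- tibble(gene_id = ids, program = prog)
  }
  if (preset$n_background_genes > 0) {
    ids <- sprintf("BG.%04d", seq_len(preset$n_background_genes))
    rows[["background"]] <- matrix(preset$baseline_log2, nrow = length(ids),
                                   ncol = nrow(grid),
                                   dimnames = list(ids, sample_id))
    truth[["background"]] <- tibble(gene_id = ids, program = "background")
  }
  mu_mat <- do.call(rbind, rows)
  log2_mat <- withr::with_seed(preset$seed, {
    mu_mat + matrix(rnorm(length(mu_mat), sd = preset$noise_sigma),
                    nrow = nrow(mu_mat))
  })
  dimnames(log2_mat) <- dimnames(mu_mat)
  list(expr = expr_tbl(2 ^ log2_mat, "linear"),
       meta = meta,
       true_programs = dplyr::bind_rows(truth))
}
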