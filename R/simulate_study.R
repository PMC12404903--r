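#' Simulate a complete multi-stage imaging study on disk
#'
#' Generates one synthetic stack per animal x section for a single brain
#' region across the five study groups (four estrous stages plus
#' lactation), writes each as a TIFF fixture, and returns the run
#' manifest ready for [run_pipeline()] together with the planted
#' expression levels. The stage effect is carried by the fraction of
#' cells expressing probe 2 (the lactation-regulated transcript), while
#' probe 1 expression is constant across stages — mirroring a study in
#' which the number of expressing cells, not the expression per cell,
#' changes between groups.
#'
#' Stacks are deliberately smaller than full-field acquisitions so a
#' whole study stays desk-sized; the per-stage expressing fractions are
#' chosen to reproduce the qualitative ordering of the calibrated group
#' means (lactation far above all cycle stages, a proestrous elevation,
#' near-baseline metestrus/diestrus).
#'
#' @param out_dir directory that will receive one subdirectory per stack.
#' @param region region label recorded in the manifest.
#' @param stages group labels.
#' @param expressing_frac_probe2 named per-stage fraction of cells
#'   expressing probe 2.
#' @param expressing_frac_probe1 stage-independent expressing fraction
#'   for probe 1.
#' @param n_animals_per_stage,sections_per_animal design size.
#' @param shape_zyx,n_nuclei per-stack scene geometry.
#' @param dots_mean,dots_dispersion negative binomial dot count of an
#'   expressing cell.
#' @param seed base seed; each stack uses `seed + stack index`.
#' @return list with `manifest` (data.frame for [run_config()]),
#'   `planted` (per-stage planted mean expressing cells per section) and
#'   `n_stacks`.
#' @export
simulate_study <- function(out_dir, region = "ARN",
                           stages = c("metestrus", "diestrus", "proestrus",
                                      "estrus", "lactation"),
                           expressing_frac_probe2 = c(metestrus = 0.07,
                                                      diestrus = 0.15,
                                                      proestrus = 0.45,
                                                      estrus = 0.22,
                                                      lactation = 0.90),
                           expressing_frac_probe1 = 0.4,
                           n_animals_per_stage = 4L,
                           sections_per_animal = 3L,
                           shape_zyx = c(4L, 128L, 128L), n_nuclei = 24L,
                           dots_mean = 12, dots_dispersion = 3,
                           seed = 1L) {
  if (!all(stages %in% names(expressing_frac_probe2)))
    .stopf("expressing_frac_probe2 must name every stage")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  idx <- 0L
  for (stage in stages) for (a in seq_len(n_animals_per_stage))
    for (sec in seq_len(sections_per_animal)) {
      idx <- idx + 1L
      cfg <- sim_image_config(
        shape_zyx = shape_zyx, n_nuclei = n_nuclei,
        nucleus_radius_um_range = c(2.6, 3.2),
        dots_per_cell_dist = list(
          probe1 = list(pi0 = 1 - expressing_frac_probe1,
                        mean = dots_mean, dispersion = dots_dispersion),
          probe2 = list(pi0 = 1 - expressing_frac_probe2[[stage]],
                        mean = dots_mean, dispersion = dots_dispersion)),
        seed = seed + idx)
      sim <- simulate_stack(cfg)
      dir_i <- file.path(out_dir, sprintf("stack%03d", idx))
      write_fixture(sim$stack, sim$truth, dir_i, config = cfg)
      rows[[idx]] <- data.frame(
        stack_path = file.path(dir_i, "stack.tif"),
        label_path = NA_character_,
        animal_id = sprintf("%s_%02d", stage, a),
        stage = stage, region = region, section_id = sec)
    }
  planted <- data.frame(stage = stages,
                        planted_mean_positive =
                          n_nuclei * unname(expressing_frac_probe2[stages]))
  list(manifest = do.call(rbind, rows), planted = planted, n_stacks = idx)
}
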