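#' Default per-section positive-cell means by region and stage
#'
#' The printed group means of the quantified experiment anchor the
#' defaults: ARN 12.3 (diestrus) and 178.2 (lactation), DMN 16.3 (estrus)
#' and 152.5 (lactation), MEPD 12.8 (diestrus) and 159.6 (lactation)
#' positive cells per section. Stages without a printed mean are filled
#' with values close to the printed baseline of their region, including a
#' moderate proestrous elevation in the ARN.
#'
#' @return data.frame with columns `region`, `stage`, `mean`.
#' @export
default_group_means <- function() {
  data.frame(
    region = rep(c("ARN", "DMN", "MEPD"), each = 5),
    stage = rep(c("metestrus", "diestrus", "proestrus", "estrus", "lactation"), 3),
    mean = c(12.0, 12.3, 30.0, 14.0, 178.2,
             18.0, 20.0, 22.0, 16.3, 152.5,
             14.0, 12.8, 15.0, 16.0, 159.6))
}

#' Configuration for the group-level count simulator
#'
#' Emulates the study design: 4 estrous stages plus lactation day 11,
#' 3-4 animals per group, three sections per brain region per animal.
#' Section counts are negative binomial around a (region, stage) mean
#' scaled by a lognormal per-animal multiplier (mean-one, so the
#' configured means are marginal means).
#'
#' @param stages,regions factor level labels.
#' @param n_animals_per_stage animals per stage.
#' @param sections_per_animal sections per region per animal.
#' @param mean_cells_per_section data.frame (`region`, `stage`, `mean`)
#'   giving the expected positive cells per section; must cover every
#'   requested region x stage combination.
#' @param nb_dispersion negative binomial size parameter (> 0).
#' @param animal_effect_sd_log sd of the log-normal animal multiplier
#'   (0 disables between-animal variation).
#' @param deterministic if `TRUE`, counts are `round(mean x multiplier)`
#'   with no sampling noise (the infinite-dispersion limit).
#' @param seed integer RNG seed.
#' @return list of class `group_sim_config`.
#' @export
group_sim_config <- function(stages = c("metestrus", "diestrus", "proestrus",
                                        "estrus", "lactation"),
                             regions = c("ARN", "DMN", "MEPD"),
                             n_animals_per_stage = 4L,
                             sections_per_animal = 3L,
                             mean_cells_per_section = default_group_means(),
                             nb_dispersion = 5,
                             animal_effect_sd_log = 0.2,
                             deterministic = FALSE,
                             seed = 1L) {
  if (n_animals_per_stage < 1L || sections_per_animal < 1L)
    .stopf("animal and section counts must be >= 1")
  if (nb_dispersion <= 0) .stopf("nb_dispersion must be > 0")
  if (animal_effect_sd_log < 0) .stopf("animal_effect_sd_log must be >= 0")
  m <- mean_cells_per_section
  if (!all(c("region", "stage", "mean") %in% names(m)))
    .stopf("mean_cells_per_section needs columns region, stage, mean")
  if (any(m$mean < 0)) .stopf("means must be >= 0")
  want <- expand.grid(region = regions, stage = stages,
                      stringsAsFactors = FALSE)
  key <- paste(m$region, m$stage)
  missing <- !(paste(want$region, want$stage) %in% key)
  if (any(missing))
    .stopf("mean_cells_per_section is missing %s; known keys: %s",
           paste(paste(want$region, want$stage)[missing], collapse = ", "),
           paste(sort(key), collapse = ", "))
  structure(as.list(environment())[c("stages", "regions",
                                     "n_animals_per_stage",
                                     "sections_per_animal",
                                     "mean_cells_per_section",
                                     "nb_dispersion", "animal_effect_sd_log",
                                     "deterministic", "seed")],
            class = "group_sim_config")
}

#' Simulate a group-level positive-cell count table
#'
#' @param config a [group_sim_config()].
#' @return data.frame (`animal_id`, `stage`, `region`, `section_id`,
#'   `cells_positive`) with one row per animal x region x section;
#'   `(animal_id, region, section_id)` is unique. Deterministic under a
#'   fixed seed.
#' @export
simulate_group_counts <- function(config = group_sim_config()) {
  stopifnot(inherits(config, "group_sim_config"))
  withr::with_seed(config$seed, {
    m <- config$mean_cells_per_section
    rows <- list()
    for (stage in config$stages) {
      for (a in seq_len(config$n_animals_per_stage)) {
        animal_id <- sprintf("%s_%02d", stage, a)
        mult <- if (config$animal_effect_sd_log > 0)
          exp(stats::rnorm(1, -config$animal_effect_sd_log^2 / 2,
                           config$animal_effect_sd_log)) else 1
        for (region in config$regions) {
          mu <- m$mean[m$region == region & m$stage == stage][1] * mult
          k <- if (config$deterministic) rep(.round_half_up(mu),
                                             config$sections_per_animal)
               else stats::rnbinom(config$sections_per_animal,
                                   size = config$nb_dispersion, mu = mu)
          rows[[length(rows) + 1L]] <-
            data.frame(animal_id = animal_id, stage = stage, region = region,
                       section_id = seq_len(config$sections_per_animal),
                       cells_positive = as.integer(k))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
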