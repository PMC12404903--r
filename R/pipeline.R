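#' Pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: the input
#' manifest (one row per stack: `stack_path`, optional `label_path` for
#' externally segmented nuclei, and the design metadata `animal_id`,
#' `stage`, `region`, `section_id`), the stage parameters, and the output
#' directory. The positivity threshold is always derived once from the
#' pooled counts of the whole run (one threshold per probe per run).
#'
#' @param manifest data.frame as described above, or path to a CSV.
#' @param output_dir directory for all outputs (created if needed).
#' @param seg a [seg_params()] object (used when a row has no
#'   `label_path`).
#' @param dilation a [dilation_params()] object.
#' @param detect a [spot_detect_params()] object, applied to both probe
#'   channels, or a named list `list(probe1 = ..., probe2 = ...)`.
#' @param rule a [positivity_rule()].
#' @param stats_unit `"animal"` (Kruskal-Wallis over per-animal means,
#'   default) or `"section"`.
#' @param seed integer recorded in the run report (the pipeline itself is
#'   deterministic; the seed documents the provenance of simulated
#'   inputs).
#' @return list of class `run_config`.
#' @export
run_config <- function(manifest, output_dir, seg = seg_params(),
                       dilation = dilation_params(),
                       detect = spot_detect_params(),
                       rule = positivity_rule(),
                       stats_unit = c("animal", "section"), seed = 1L) {
  stats_unit <- match.arg(stats_unit)
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("stack_path", "animal_id", "stage", "region", "section_id")
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    .stopf("manifest must be a non-empty data.frame")
  if (!all(need %in% names(manifest)))
    .stopf("manifest needs columns %s", paste(need, collapse = ", "))
  if (!"label_path" %in% names(manifest)) manifest$label_path <- NA_character_
  missing <- !file.exists(manifest$stack_path)
  if (any(missing))
    .stopf("stack not found: %s", manifest$stack_path[which(missing)[1]])
  if (inherits(detect, "spot_detect_params"))
    detect <- list(probe1 = detect, probe2 = detect)
  structure(list(manifest = manifest, output_dir = output_dir, seg = seg,
                 dilation = dilation, detect = detect, rule = rule,
                 stats_unit = stats_unit, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full quantification pipeline
#'
#' For every stack in the manifest: segment nuclei (or load external
#' labels), dilate into cell ROIs, detect spots in both probe channels,
#' assign them and tabulate per-cell counts. Then, pooled over the whole
#' run: derive one positivity threshold per probe, classify cells,
#' summarise dual-probe co-expression per region, aggregate positive-cell
#' counts per section and per animal, and run Kruskal-Wallis plus Dunn's
#' comparisons across stages within each region and probe. All
#' intermediates and results are written under `output_dir` as CSV/JSON;
#' identical inputs produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list (`report`, `cell_counts`, `thresholds`,
#'   `section_counts`, `animal_means`, `kw`, `dunn`, `coexpression`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mf <- config$manifest
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stack_dir <- file.path(out_dir, "stacks")
  if (!dir.exists(stack_dir)) dir.create(stack_dir)

  tables <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    stem <- sprintf("%s_%s_s%s", row$animal_id, row$region, row$section_id)
    res <- tryCatch({
      stack <- read_stack(row$stack_path)
      labels <- if (!is.na(row$label_path) && nzchar(row$label_path))
        load_labels(row$label_path, companion_shape = dim(stack$voxels)[-1])
      else segment_nuclei(stack, config$seg)
      rois <- dilate_labels(labels, config$dilation)
      write_labels(rois, file.path(stack_dir, paste0(stem, "_rois.tif")),
                   pixel_size_um = stack$pixel_size_um,
                   z_step_um = stack$z_step_um)
      spots <- rbind(
        assign_spots(detect_spots_stack(stack, "probe1",
                                        config$detect$probe1), rois),
        assign_spots(detect_spots_stack(stack, "probe2",
                                        config$detect$probe2), rois))
      write_spots_csv(spots, file.path(stack_dir, paste0(stem, "_spots.csv")))
      tab <- tabulate_counts(spots, rois,
                             meta = list(section_id = row$section_id,
                                         animal_id = row$animal_id,
                                         region = row$region,
                                         stage = row$stage),
                             probe_channels =
                               stack$channel_roles[c("probe1", "probe2")])
      attr(tab, "n_spots") <- nrow(spots)
      tab
    }, error = function(e)
      .stopf("pipeline failed on stack %s (%s): %s", row$stack_path, stem,
             conditionMessage(e)))
    tables[[i]] <- res
  }
  n_spots_total <- sum(vapply(tables, function(t)
    attr(t, "n_spots") %||% 0L, 0L))
  cells <- do.call(rbind, tables)

  thresholds <- c(
    probe1 = positivity_threshold(cells$count_probe1, config$rule),
    probe2 = positivity_threshold(cells$count_probe2, config$rule))
  cells <- classify_positive(cells, thresholds, config$rule)
  utils::write.csv(cells, file.path(out_dir, "cell_counts.csv"),
                   row.names = FALSE)

  key <- interaction(cells$animal_id, cells$region, cells$section_id,
                     drop = TRUE)
  section_counts <- do.call(rbind, lapply(split(seq_len(nrow(cells)), key),
                                          function(i) {
    data.frame(animal_id = cells$animal_id[i][1], stage = cells$stage[i][1],
               region = cells$region[i][1],
               section_id = cells$section_id[i][1],
               n_cells = length(i),
               positive_probe1 = sum(cells$positive_probe1[i]),
               positive_probe2 = sum(cells$positive_probe2[i]))
  }))
  section_counts <- section_counts[order(section_counts$region,
                                         section_counts$stage,
                                         section_counts$animal_id,
                                         section_counts$section_id), ]
  rownames(section_counts) <- NULL
  utils::write.csv(section_counts,
                   file.path(out_dir, "section_positive_counts.csv"),
                   row.names = FALSE)

  coex <- lapply(split(seq_len(nrow(cells)), cells$region), function(i)
    coexpression_summary(cells[i, , drop = FALSE]))
  coex_df <- do.call(rbind, lapply(names(coex), function(r) {
    s <- coex[[r]]
    data.frame(region = r, n_cells = s$n_cells, n_pos_A = s$n_pos_A,
               n_pos_B = s$n_pos_B, n_dual = s$n_dual,
               pct_A_that_are_B = s$pct_A_that_are_B,
               pct_B_that_are_A = s$pct_B_that_are_A)
  }))
  utils::write.csv(coex_df, file.path(out_dir, "coexpression.csv"),
                   row.names = FALSE)

  kw_rows <- list(); dunn_rows <- list(); animal_means <- list()
  for (region in sort(unique(section_counts$region))) {
    sc <- section_counts[section_counts$region == region, ]
    for (probe in c("probe1", "probe2")) {
      design <- data.frame(animal_id = sc$animal_id, stage = sc$stage,
                           region = region, section_id = sc$section_id,
                           cells_positive = sc[[paste0("positive_", probe)]])
      am <- aggregate_per_animal(design)
      animal_means[[paste(region, probe)]] <- cbind(probe = probe, am)
      values <- if (config$stats_unit == "animal")
        split(am$mean_cells_per_section, am$stage)
      else split(design$cells_positive, design$stage)
      values <- values[vapply(values, length, 0L) > 0]
      if (length(values) >= 2L && sum(lengths(values)) >= 3L) {
        kw <- kruskal_wallis(values)
        kw_rows[[paste(region, probe)]] <-
          data.frame(region = region, probe = probe, H = kw$H, df = kw$df,
                     p = kw$p)
        dn <- dunn_posthoc(values)
        dunn_rows[[paste(region, probe)]] <- cbind(region = region,
                                                   probe = probe, dn)
      }
    }
  }
  kw_df <- if (length(kw_rows)) do.call(rbind, kw_rows) else NULL
  dunn_df <- if (length(dunn_rows)) do.call(rbind, dunn_rows) else NULL
  am_df <- do.call(rbind, animal_means)
  rownames(am_df) <- NULL
  utils::write.csv(am_df, file.path(out_dir, "animal_means.csv"),
                   row.names = FALSE)
  if (!is.null(kw_df)) {
    rownames(kw_df) <- NULL
    utils::write.csv(kw_df, file.path(out_dir, "stats_kw.csv"),
                     row.names = FALSE)
  }
  if (!is.null(dunn_df)) {
    rownames(dunn_df) <- NULL
    utils::write.csv(dunn_df, file.path(out_dir, "stats_dunn.csv"),
                     row.names = FALSE)
  }

  report <- list(
    n_stacks = nrow(mf),
    stages = as.list(table(mf$stage)),
    regions = as.list(table(mf$region)),
    thresholds = as.list(thresholds),
    rule = unclass(config$rule),
    n_cells_total = nrow(cells),
    n_spots_total = n_spots_total,
    stats_unit = config$stats_unit,
    seed = config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, cell_counts = cells,
                 thresholds = thresholds, section_counts = section_counts,
                 animal_means = am_df, kw = kw_df, dunn = dunn_df,
                 coexpression = coex))
}
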