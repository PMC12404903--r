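#' Positive-cell classification rule
#'
#' The positivity threshold for a probe is derived from the per-cell dot
#' count distribution of the whole run: `mean - k_sd x SD`, rounded
#' half-up to whole dots and floored at 1. By default cells with zero
#' dots are excluded from the distribution — with the sparse expression
#' typical of these data, including them would drive the threshold
#' strongly negative — and positivity uses an inclusive comparator.
#'
#' @param k_sd standard-deviation multiplier (default 2).
#' @param include_zero_cells include zero-count cells in the threshold
#'   distribution.
#' @param comparator `"ge"` (count >= threshold, default) or `"gt"`.
#' @param rounding `"half_up"` (default) or `"none"`.
#' @return list of class `positivity_rule`.
#' @export
positivity_rule <- function(k_sd = 2, include_zero_cells = FALSE,
                            comparator = c("ge", "gt"),
                            rounding = c("half_up", "none")) {
  comparator <- match.arg(comparator)
  rounding <- match.arg(rounding)
  if (k_sd < 0) .stopf("k_sd must be >= 0")
  structure(list(k_sd = k_sd, include_zero_cells = include_zero_cells,
                 comparator = comparator, rounding = rounding),
            class = "positivity_rule")
}

#' Assign detected spots to cell ROIs
#'
#' Each spot takes the label value at its nearest voxel (half-up rounded
#' z, y, x); 0 means background. Input order is preserved.
#'
#' @param spots spot data.frame with columns `z`, `y`, `x` (1-based).
#' @param rois a [label_volume()] of (dilated) cell ROIs.
#' @return `spots` with `roi_label` filled in.
#' @export
assign_spots <- function(spots, rois) {
  stopifnot(inherits(rois, "label_volume"))
  d <- dim(rois$labels)
  if (nrow(spots) == 0L) { spots$roi_label <- integer(0); return(spots) }
  iz <- .round_half_up(spots$z); iy <- .round_half_up(spots$y)
  ix <- .round_half_up(spots$x)
  bad <- which(iz < 1 | iz > d[1] | iy < 1 | iy > d[2] | ix < 1 | ix > d[3])
  if (length(bad))
    .stopf("spot %d at (z=%.2f, y=%.2f, x=%.2f) lies outside the %s volume",
           bad[1], spots$z[bad[1]], spots$y[bad[1]], spots$x[bad[1]],
           paste(d, collapse = "x"))
  spots$roi_label <- rois$labels[cbind(iz, iy, ix)]
  spots
}

#' Tabulate per-cell per-probe dot counts
#'
#' One row per ROI label in `rois` (cells with zero spots included);
#' count columns tally the assigned spots per probe channel. Column sums
#' over cells equal the number of spots assigned to any cell (spots on
#' background, `roi_label = 0`, are excluded but conserved in the input).
#'
#' @param spots assigned spot data.frame (see [assign_spots()]) with a
#'   `channel` column.
#' @param rois the [label_volume()] used for assignment.
#' @param meta optional named list (`section_id`, `animal_id`, `region`,
#'   `stage`) replicated onto every row.
#' @param probe_channels named integer vector mapping `probe1`/`probe2`
#'   to channel indices in `spots$channel`.
#' @return data.frame of class `cell_counts`: `cell_id`, `section_id`,
#'   `animal_id`, `region`, `stage`, `count_probe1`, `count_probe2`,
#'   `positive_probe1`, `positive_probe2` (NA until
#'   [classify_positive()]).
#' @export
tabulate_counts <- function(spots, rois, meta = NULL,
                            probe_channels = c(probe1 = 1L, probe2 = 2L)) {
  stopifnot(inherits(rois, "label_volume"))
  ids <- sort(unique(rois$labels[rois$labels > 0L]))
  meta <- utils::modifyList(list(section_id = 1L, animal_id = NA_character_,
                                 region = NA_character_, stage = NA_character_),
                            as.list(meta %||% list()))
  count_for <- function(ch) {
    sel <- spots$channel == ch & spots$roi_label > 0L
    tab <- table(factor(spots$roi_label[sel], levels = ids))
    as.integer(tab)
  }
  out <- data.frame(cell_id = ids,
                    section_id = meta$section_id, animal_id = meta$animal_id,
                    region = meta$region, stage = meta$stage,
                    count_probe1 = count_for(probe_channels[["probe1"]]),
                    count_probe2 = count_for(probe_channels[["probe2"]]),
                    positive_probe1 = NA, positive_probe2 = NA)
  class(out) <- c("cell_counts", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Data-driven positivity threshold for one probe
#'
#' `threshold = mean - k_sd x sample SD` of the per-cell dot count
#' distribution (zero-count cells excluded under the default rule),
#' rounded half-up to an integer and floored at 1 (with a warning when
#' the raw value is below 1).
#'
#' @param counts integer vector of per-cell dot counts for one probe.
#' @param rule a [positivity_rule()].
#' @return numeric threshold in dots.
#' @examples
#' positivity_threshold(c(4, 6, 8, 10, 12))  # mean 8, SD sqrt(10) -> 2
#' @export
positivity_threshold <- function(counts, rule = positivity_rule()) {
  stopifnot(inherits(rule, "positivity_rule"))
  eligible <- if (rule$include_zero_cells) counts else counts[counts > 0]
  if (length(eligible) < 2L)
    .stopf("need at least 2 eligible cells to estimate a threshold (have %d)",
           length(eligible))
  thr <- mean(eligible) - rule$k_sd * stats::sd(eligible)
  if (rule$rounding == "half_up") thr <- .round_half_up(thr)
  if (thr < 1) {
    warning(sprintf("raw threshold %.3f below 1 dot; floored to 1", thr),
            call. = FALSE)
    thr <- 1
  }
  thr
}

#' Flag positive cells at given per-probe thresholds
#'
#' @param table a `cell_counts` data.frame ([tabulate_counts()]).
#' @param thresholds named numeric (`probe1`, `probe2`), each >= 1.
#' @param rule a [positivity_rule()] (only the comparator is used here).
#' @return `table` with `positive_probe1`/`positive_probe2` filled.
#' @export
classify_positive <- function(table, thresholds, rule = positivity_rule()) {
  stopifnot(inherits(rule, "positivity_rule"))
  if (!all(c("probe1", "probe2") %in% names(thresholds)))
    .stopf("thresholds must name probe1 and probe2")
  if (any(thresholds < 1)) .stopf("thresholds must be >= 1")
  cmp <- if (rule$comparator == "ge") `>=` else `>`
  table$positive_probe1 <- cmp(table$count_probe1, thresholds[["probe1"]])
  table$positive_probe2 <- cmp(table$count_probe2, thresholds[["probe2"]])
  table
}

#' Dual-probe co-expression summary
#'
#' Counts cells positive for each probe and for both, and reports the
#' conditional percentages (what fraction of probe-A-positive cells are
#' also probe-B-positive, and vice versa) pooled over all cells and as
#' the mean of per-section percentages. Undefined percentages (no
#' positive cells in the denominator) are reported as `NA`, never 0.
#'
#' @param table a classified `cell_counts` data.frame.
#' @param probe_a,probe_b probe names (`"probe1"`, `"probe2"`).
#' @return list of class `coexpression_summary`: `n_cells`, `n_pos_A`,
#'   `n_pos_B`, `n_dual`, `pct_A_that_are_B`, `pct_B_that_are_A`,
#'   `per_section` (the same quantities by section) and
#'   `per_section_mean_pct_A_that_are_B` / `..._B_that_are_A`.
#' @export
coexpression_summary <- function(table, probe_a = "probe1", probe_b = "probe2") {
  pa <- table[[paste0("positive_", probe_a)]]
  pb <- table[[paste0("positive_", probe_b)]]
  if (any(is.na(pa)) || any(is.na(pb)))
    .stopf("positivity flags missing; run classify_positive() first")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  pooled <- list(n_cells = nrow(table), n_pos_A = sum(pa), n_pos_B = sum(pb),
                 n_dual = sum(pa & pb))
  pooled$pct_A_that_are_B <- pct(pooled$n_dual, pooled$n_pos_A)
  pooled$pct_B_that_are_A <- pct(pooled$n_dual, pooled$n_pos_B)
  per_sec <- do.call(rbind, lapply(split(seq_len(nrow(table)),
                                         table$section_id), function(i) {
    d <- sum(pa[i] & pb[i])
    data.frame(section_id = table$section_id[i][1], n_cells = length(i),
               n_pos_A = sum(pa[i]), n_pos_B = sum(pb[i]), n_dual = d,
               pct_A_that_are_B = pct(d, sum(pa[i])),
               pct_B_that_are_A = pct(d, sum(pb[i])))
  }))
  rownames(per_sec) <- NULL
  structure(c(pooled,
              list(per_section = per_sec,
                   per_section_mean_pct_A_that_are_B =
                     mean(per_sec$pct_A_that_are_B, na.rm = TRUE),
                   per_section_mean_pct_B_that_are_A =
                     mean(per_sec$pct_B_that_are_A, na.rm = TRUE))),
            class = "coexpression_summary")
}
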