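#' Aggregate section counts to per-animal means
#'
#' The unit of analysis for group comparisons is the animal: section
#' counts are averaged per animal within each region, matching designs
#' with a handful of animals per group and several sections per animal.
#'
#' @param design data.frame with columns `animal_id`, `stage`, `region`,
#'   `section_id`, `cells_positive` (as from [simulate_group_counts()]).
#' @return data.frame (`animal_id`, `stage`, `region`,
#'   `mean_cells_per_section`), one row per animal x region.
#' @export
aggregate_per_animal <- function(design) {
  need <- c("animal_id", "stage", "region", "cells_positive")
  if (!all(need %in% names(design)))
    .stopf("design needs columns %s", paste(need, collapse = ", "))
  out <- stats::aggregate(cells_positive ~ animal_id + stage + region,
                          data = design, FUN = mean)
  names(out)[names(out) == "cells_positive"] <- "mean_cells_per_section"
  out <- out[order(out$region, out$stage, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.rank_setup <- function(groups) {
  if (length(groups) < 2L) .stopf("need at least 2 groups")
  if (any(vapply(groups, length, 0L) == 0L)) .stopf("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N < 3L) .stopf("need at least 3 observations in total")
  r <- rank(pooled)                      # mid-ranks for ties
  idx <- rep(seq_along(groups), vapply(groups, length, 0L))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  list(N = N, r = r, idx = idx, tie_term = tie_term)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Computed from the rank formula: with pooled mid-ranks, group mean
#' ranks \eqn{\bar R_i} and tie groups of size \eqn{t},
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_i n_i \bar R_i^2 - 3(N+1)}
#'            {1 - \sum_t (t^3 - t) / (N^3 - N)}}
#' and the p-value is the chi-square upper tail with `k - 1` degrees of
#' freedom. When all pooled values are identical the tie-correction
#' denominator vanishes; by convention the result is then `H = 0, p = 1`.
#'
#' @param groups list (optionally named) of numeric vectors, one per group.
#' @return object of class `kw_result`: `H`, `df`, `p`, and
#'   `group_summary` (per-group `n`, `mean`, `sem`, `mean_rank`).
#' @export
kruskal_wallis <- function(groups) {
  s <- .rank_setup(groups)
  k <- length(groups)
  n_i <- vapply(groups, length, 0L)
  rbar <- vapply(seq_len(k), function(i) mean(s$r[s$idx == i]), 0)
  C <- 1 - s$tie_term / (s$N^3 - s$N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- (12 / (s$N * (s$N + 1)) * sum(n_i * rbar^2) - 3 * (s$N + 1)) / C
    H <- max(H, 0)
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  nm <- if (is.null(names(groups))) paste0("group", seq_len(k)) else names(groups)
  summ <- data.frame(group = nm, n = n_i,
                     mean = vapply(groups, mean, 0),
                     sem = vapply(groups, function(g)
                       stats::sd(g) / sqrt(length(g)), 0),
                     mean_rank = rbar)
  structure(list(H = H, df = k - 1L, p = p, group_summary = summ),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis %.4g (df = %d), p = %.4g\n", x$H, x$df, x$p))
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For groups `i`, `j` with mean ranks \eqn{\bar R_i, \bar R_j} over the
#' pooled mid-ranks,
#' \deqn{z = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\right)
#'     \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values and Bonferroni adjustment over the
#' requested comparisons (`p_adjusted = min(1, p_raw x m)`). When the
#' pooled data are entirely tied the variance vanishes; the convention is
#' `z = 0, p = 1`.
#'
#' @param groups list of numeric vectors (named names are used in the
#'   output).
#' @param comparisons list of integer or name pairs; default all pairs.
#' @param adjust multiplicity adjustment; only `"bonferroni"` is offered.
#' @return data.frame of class `dunn_result`: `group_i`, `group_j`,
#'   `mean_rank_diff`, `z`, `p_raw`, `p_adjusted`, `n_comparisons`.
#' @export
dunn_posthoc <- function(groups, comparisons = NULL,
                         adjust = c("bonferroni")) {
  adjust <- match.arg(adjust)
  s <- .rank_setup(groups)
  k <- length(groups)
  nm <- if (is.null(names(groups))) paste0("group", seq_len(k)) else names(groups)
  n_i <- vapply(groups, length, 0L)
  rbar <- vapply(seq_len(k), function(i) mean(s$r[s$idx == i]), 0)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(k, 2, simplify = FALSE)
  } else {
    comparisons <- lapply(comparisons, function(p) {
      if (is.character(p)) p <- match(p, nm)
      if (any(is.na(p)) || length(p) != 2L) .stopf("invalid comparison pair")
      as.integer(p)
    })
  }
  if (!length(comparisons)) .stopf("comparisons must be non-empty")
  m <- length(comparisons)
  var_base <- s$N * (s$N + 1) / 12 - s$tie_term / (12 * (s$N - 1))
  out <- do.call(rbind, lapply(comparisons, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt(var_base * (1 / n_i[i] + 1 / n_i[j]))
    diff <- rbar[i] - rbar[j]
    if (se <= 0) {
      z <- 0; p_raw <- 1
    } else {
      z <- diff / se
      p_raw <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group_i = nm[i], group_j = nm[j], mean_rank_diff = diff,
               z = z, p_raw = p_raw,
               p_adjusted = min(1, p_raw * m), n_comparisons = m)
  }))
  rownames(out) <- NULL
  class(out) <- c("dunn_result", "data.frame")
  out
}
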