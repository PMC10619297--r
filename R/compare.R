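# Group-comparison layer: Mann-Whitney-Wilcoxon with Bonferroni correction,
# Kruskal-Wallis for cumulative error, Cohen's d, and age-bin contrasts.

#' Pairwise Mann-Whitney-Wilcoxon tests with Bonferroni correction
#'
#' Two-sided rank-sum test for each requested pair of groups (exact null
#' distribution for small tie-free samples, normal approximation with tie
#' correction otherwise, as in [stats::wilcox.test()]). Bonferroni
#' correction multiplies each raw p-value by `n_comparisons`, capped at 1.
#' The reported U statistic is `min(U_ab, U_ba)` so it does not depend on
#' pair orientation; `U_ab + U_ba = n_a * n_b` always.
#'
#' @param values_by_group Named list of numeric vectors.
#' @param pairs List of length-2 character vectors naming group pairs;
#'   default all pairs.
#' @param n_comparisons Size of the comparison family used for the
#'   correction (default: number of pairs tested).
#' @param metric Optional metric name carried into the result.
#' @param alpha Significance threshold applied to the corrected p-value
#'   (default 0.05).
#' @return data.table: group_a, group_b, metric, u_stat, p_raw,
#'   p_bonferroni, n_comparisons, significant.
#' @export
mwu_bonferroni <- function(values_by_group, pairs = NULL,
                           n_comparisons = NULL, metric = NA_character_,
                           alpha = 0.05) {
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  if (any(vapply(values_by_group, length, integer(1)) < 2L))
    stop("insufficient data: every group needs at least 2 values",
         call. = FALSE)
  if (is.null(pairs)) {
    nm <- names(values_by_group)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  n_comparisons <- n_comparisons %||% length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- values_by_group[[pr[1]]]; b <- values_by_group[[pr[2]]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    u_ab <- unname(wt$statistic)
    u <- min(u_ab, length(a) * length(b) - u_ab)
    p_b <- min(1, wt$p.value * n_comparisons)
    data.table::data.table(group_a = pr[1], group_b = pr[2], metric = metric,
                           u_stat = u, p_raw = wt$p.value,
                           p_bonferroni = p_b,
                           n_comparisons = as.integer(n_comparisons),
                           significant = p_b <= alpha)
  })
  data.table::rbindlist(rows)
}

#' Kruskal-Wallis test on final cumulative errors
#'
#' Compares the distributions of final cumulative-error values across
#' groups. Significance is judged at 0.01 / 4 = 0.0025, a Bonferroni-style
#' split of 0.01 over four comparison settings (two sampling resolutions by
#' two alignment choices).
#'
#' @param final_cum_by_group Named list (>= 2 groups, each >= 2 values) of
#'   final cumulative errors.
#' @param threshold Significance threshold (default 0.0025).
#' @return list(H, p, significant).
#' @export
kruskal_cumerr <- function(final_cum_by_group, threshold = 0.01 / 4) {
  stopifnot(is.list(final_cum_by_group), length(final_cum_by_group) >= 2)
  if (any(vapply(final_cum_by_group, length, integer(1)) < 2L))
    stop("insufficient data: every group needs at least 2 values",
         call. = FALSE)
  allv <- unlist(final_cum_by_group, use.names = FALSE)
  if (length(unique(allv)) == 1L) {
    warning("all values tied across groups; H statistic undefined, using 0",
            call. = FALSE)
    return(list(H = 0, p = 1, significant = FALSE))
  }
  g <- factor(rep(names(final_cum_by_group),
                  vapply(final_cum_by_group, length, integer(1))))
  kt <- stats::kruskal.test(allv, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       significant = kt$p.value <= threshold)
}

#' Cohen's d effect size
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled sd
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' Antisymmetric in its arguments.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("insufficient data: each group needs at least 2 values",
         call. = FALSE)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0)
    stop("undefined metric: zero pooled standard deviation", call. = FALSE)
  (mean(a) - mean(b)) / sp
}

#' Age-bin contrasts of median nightly maximum temperature
#'
#' Tests every (below-50, 50-or-above) age-bin pair on the per-participant
#' median nightly temperature maximum, with a Bonferroni family of
#' `n_comparisons` tests (default 15, the full set of bin pairs in a
#' six-bin design).
#'
#' @param medians data.frame with pid, age_bin, median_temp_max.
#' @param split_age Boundary age (default 50): a bin is "below" when its
#'   label's lower bound is under this age.
#' @param n_comparisons Bonferroni family size (default 15).
#' @param alpha Threshold on the corrected p (default 0.05).
#' @return data.table of [mwu_bonferroni()] results (empty when no
#'   below/above pair has data); bins with fewer than 2 participants are
#'   skipped with a warning.
#' @export
age_bin_contrasts <- function(medians, split_age = 50, n_comparisons = 15,
                              alpha = 0.05) {
  dt <- data.table::as.data.table(medians)
  stopifnot(all(c("age_bin", "median_temp_max") %in% names(dt)))
  bins <- sort(unique(dt$age_bin))
  lo <- as.numeric(sub("-.*$", "", bins))
  below <- bins[lo < split_age]; above <- bins[lo >= split_age]
  vals <- lapply(stats::setNames(bins, bins),
                 function(b) dt[age_bin == b, median_temp_max])
  small <- names(vals)[vapply(vals, length, integer(1)) < 2L]
  if (length(small)) {
    warning(sprintf("skipping age bin(s) with < 2 participants: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    below <- setdiff(below, small); above <- setdiff(above, small)
  }
  if (!length(below) || !length(above))
    return(data.table::data.table(group_a = character(), group_b = character(),
                                  metric = character(), u_stat = numeric(),
                                  p_raw = numeric(), p_bonferroni = numeric(),
                                  n_comparisons = integer(),
                                  significant = logical()))
  pairs <- unlist(lapply(below, function(b) lapply(above, function(a) c(b, a))),
                  recursive = FALSE)
  mwu_bonferroni(vals, pairs, n_comparisons = n_comparisons,
                 metric = "median_temp_max", alpha = alpha)
}
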