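#' Pearson correlation with guardrails
#'
#' Thin, validated wrapper around [stats::cor()]: both vectors must be the
#' same length (at least 3), finite, and have non-zero variance, otherwise
#' the correlation is undefined and an error is raised.
#'
#' @param x,y numeric vectors.
#' @return Pearson's r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("inputs must be finite")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("correlation undefined: zero variance")
  }
  cor(x, y)
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Standard one-way analysis of variance across groups, followed by
#' pairwise comparisons whose p-values are Bonferroni-adjusted
#' (raw p times the number of comparisons, capped at 1).
#'
#' @param data a data frame.
#' @param value,group unquoted column names of the response and the
#'   grouping variable.
#' @return an `anova_bonferroni` object; [glance()] gives the omnibus F
#'   test, [tidy()] the pairwise adjusted p-values.
#' @export
#' @examples
#' d <- data.frame(v = c(rnorm(10), rnorm(10, 3)),
#'                 g = rep(c("a", "b"), each = 10))
#' glance(anova_bonferroni(d, v, g))
anova_bonferroni <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 values")
  if (any(!is.finite(v))) abort("response must be finite")
  if (stats::var(v) == 0) abort("response is constant; ANOVA degenerate")
  fit <- aov(v ~ g)
  s <- summary(fit)[[1]]
  pw <- pairwise.t.test(v, g, p.adjust.method = "none", pool.sd = TRUE)
  m <- pw$p.value
  pairs <- which(!is.na(m), arr.ind = TRUE)
  n_comp <- nrow(pairs)
  pairwise <- tibble(
    group1 = rownames(m)[pairs[, 1]],
    group2 = colnames(m)[pairs[, 2]],
    p_raw = m[pairs],
    p_adj = pmin(1, m[pairs] * n_comp))
  structure(list(
    f_statistic = s[["F value"]][1],
    p_value = s[["Pr(>F)"]][1],
    df_between = s[["Df"]][1], df_within = s[["Df"]][2],
    pairwise = pairwise), class = "anova_bonferroni")
}

#' @export
print.anova_bonferroni <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @export
glance.anova_bonferroni <- function(x, ...) {
  tibble(statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within)
}

#' @export
tidy.anova_bonferroni <- function(x, ...) x$pairwise

#' Simulate two independent readers
#'
#' Perturbs a vector of measurements with independent multiplicative
#' lognormal noise per reader (`sigma` on the log scale) and reports the
#' inter-reader Pearson correlation — the simulation analogue of two
#' radiologists independently re-measuring the same occupation ratios.
#'
#' @param measurements numeric vector of true measurements.
#' @param noise_sigma lognormal sigma (0 gives identical readers, r = 1).
#' @param seed integer seed.
#' @return a `reader_sim` object with `readings` (tibble: `truth`,
#'   `reader1`, `reader2`) and `r`; [glance()] returns a one-row summary.
#' @export
simulate_readers <- function(measurements, noise_sigma = 0.05, seed = 1) {
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    abort("noise_sigma must be >= 0")
  }
  n <- length(measurements)
  withr::with_seed(as.integer(seed), {
    r1 <- measurements * rlnorm(n, 0, noise_sigma)
    r2 <- measurements * rlnorm(n, 0, noise_sigma)
  })
  structure(list(
    readings = tibble(truth = measurements, reader1 = r1, reader2 = r2),
    r = pearson_r(r1, r2),
    noise_sigma = noise_sigma), class = "reader_sim")
}

#' @export
print.reader_sim <- function(x, ...) {
  cat(sprintf("<reader_sim> n = %d, sigma = %g, inter-reader r = %.3f\n",
              nrow(x$readings), x$noise_sigma, x$r))
  invisible(x)
}

#' @export
glance.reader_sim <- function(x, ...) {
  tibble(n = nrow(x$readings), noise_sigma = x$noise_sigma, r = x$r)
}

#' @export
tidy.reader_sim <- function(x, ...) x$readings

#' Atrophy overestimation of the single-slice method
#'
#' Compares, between an affected group and the intact reference group,
#' the relative preservation of 3D muscle volume with the relative
#' preservation of the single-slice (Y-view) muscle surface:
#' `rv = mean volume affected / mean volume intact`,
#' `rs = mean surface affected / mean surface intact`,
#' `diff = rv - rs`, and `normalized = diff / rv` — the fraction by which
#' the single-slice method overstates atrophy relative to true volume
#' loss. Group means, not per-subject ratios, enter the statistic.
#'
#' Printed report values follow the clinical-report convention of
#' rounding every step half-up to one decimal percent, so the reported
#' normalized overestimation is `diff_pct / rv_pct` re-rounded; tidy()
#' carries both the full-precision and the report-rounded chain.
#'
#' @param mean_v_intact,mean_v_affected group mean 3D volumes (intact
#'   means must be positive).
#' @param mean_s_intact,mean_s_affected group mean Y-view muscle surface
#'   areas (any common unit; only the ratio matters, so a pre-computed
#'   ratio can be passed as `mean_s_affected` with `mean_s_intact = 1`).
#' @return an `overestimation` object; [tidy()] returns one row with
#'   `rv`, `rs`, `diff`, `normalized` and their `_pct` report-rounded
#'   counterparts; [glance()] the report-rounded percentages.
#' @export
#' @examples
#' ov <- overestimation(56.9, 31.1, 1, 0.472)
#' glance(ov)
overestimation <- function(mean_v_intact, mean_v_affected,
                           mean_s_intact, mean_s_affected) {
  vals <- c(mean_v_intact, mean_v_affected, mean_s_intact,
            mean_s_affected)
  if (any(!is.finite(vals))) abort("all group means must be finite")
  if (mean_v_intact <= 0 || mean_s_intact <= 0) {
    abort("intact group means must be positive")
  }
  rv <- mean_v_affected / mean_v_intact
  rs <- mean_s_affected / mean_s_intact
  rv_pct <- round_half_up(100 * rv, 1)
  rs_pct <- round_half_up(100 * rs, 1)
  diff_pct <- round_half_up(rv_pct - rs_pct, 1)
  structure(list(
    rv = rv, rs = rs, diff = rv - rs, normalized = (rv - rs) / rv,
    rv_pct = rv_pct, rs_pct = rs_pct, diff_pct = diff_pct,
    normalized_pct = round_half_up(100 * diff_pct / rv_pct, 1)),
    class = "overestimation")
}

#' @export
print.overestimation <- function(x, ...) {
  cat(sprintf(
    paste0("Relative volume preserved: %.1f%%; relative Y-view surface",
           " preserved: %.1f%%\n",
           "Surface deficit beyond volume loss: %.1f percentage points",
           " (%.1f%% of the volume ratio)\n"),
    x$rv_pct, x$rs_pct, x$diff_pct, x$normalized_pct))
  invisible(x)
}

#' @export
tidy.overestimation <- function(x, ...) {
  tibble(rv = x$rv, rs = x$rs, diff = x$diff, normalized = x$normalized,
         rv_pct = x$rv_pct, rs_pct = x$rs_pct, diff_pct = x$diff_pct,
         normalized_pct = x$normalized_pct)
}

#' @export
glance.overestimation <- function(x, ...) {
  tibble(rv_pct = x$rv_pct, rs_pct = x$rs_pct, diff_pct = x$diff_pct,
         normalized_pct = x$normalized_pct)
}

#' Per-group cohort summaries
#'
#' Group-wise bookkeeping of a measured cohort: size, share of the whole
#' cohort, volume and OR means and ranges, and Thomazeau stage counts
#' with percentages. Percentages are rounded half-up to one decimal, the
#' package's reporting convention.
#'
#' @param cohort data frame with at least a group column; volume, OR and
#'   stage columns are summarised when present.
#' @param group,volume,or_value,stage unquoted column names.
#' @return tibble with one row per group.
#' @export
summarize_groups <- function(cohort, group = group,
                             volume = volume_cm3, or_value = or_value,
                             stage = stage) {
  if (!nrow(cohort)) abort("cohort is empty")
  gcol <- dplyr::pull(cohort, {{ group }})
  if (any(is.na(gcol)) || any(gcol == "")) {
    abort("unknown (missing) group label in cohort")
  }
  total <- nrow(cohort)
  has <- function(nm) nm %in% names(cohort)
  vnm <- as_name(enquo(volume))
  onm <- as_name(enquo(or_value))
  snm <- as_name(enquo(stage))
  out <- cohort |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / total, 1))
  if (has(vnm)) {
    vs <- cohort |>
      dplyr::group_by({{ group }}) |>
      dplyr::summarise(volume_mean = mean({{ volume }}),
                       volume_min = min({{ volume }}),
                       volume_max = max({{ volume }}), .groups = "drop")
    out <- dplyr::left_join(out, vs, by = as_name(enquo(group)))
  }
  if (has(onm)) {
    os <- cohort |>
      dplyr::group_by({{ group }}) |>
      dplyr::summarise(or_mean = mean({{ or_value }}),
                       or_min = min({{ or_value }}),
                       or_max = max({{ or_value }}), .groups = "drop")
    out <- dplyr::left_join(out, os, by = as_name(enquo(group)))
  }
  if (has(snm)) {
    ss <- cohort |>
      dplyr::count({{ group }}, {{ stage }}, .drop = FALSE) |>
      tidyr::pivot_wider(names_from = {{ stage }}, values_from = "n",
                         names_prefix = "stage_", values_fill = 0L)
    out <- dplyr::left_join(out, ss, by = as_name(enquo(group)))
    for (st in c("I", "II", "III")) {
      cn <- paste0("stage_", st)
      if (cn %in% names(out)) {
        out[[paste0(cn, "_pct")]] <-
          round_half_up(100 * out[[cn]] / out$n, 1)
      }
    }
  }
  out
}
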