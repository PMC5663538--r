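# Cross-condition comparisons: ordinary least-squares regressions with
# Pearson correlation (as used to relate median rolling velocity to percent
# rolling across runs) and tidy dose-response tables of per-run summaries.

#' Linear regression with slope test and Pearson correlation
#'
#' Ordinary least squares of `y` on `x` with the two-sided t-test that the
#' slope is non-zero, plus Pearson's r and its significance test.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`; `x` must vary.
#' @return An object of class `chromatography_regression` with fields
#'   `slope`, `intercept`, `slope_se`, `p_slope`, `pearson_r`, `p_pearson`,
#'   `n`, and the underlying `lm` fit in `$fit`.
#' @export
#' @examples
#' r <- linear_regression(1:5, 2 * (1:5) + 1)
#' tidy(r)
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least 2 points")
  if (stats::var(x) == 0) stopf("x has zero variance: slope is undefined")
  fit <- lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))
  ct <- if (n >= 3 && is.finite(r) && abs(r) < 1)
    suppressWarnings(cor.test(x, y)) else NULL
  structure(list(
    slope = unname(cf["x", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope_se = unname(cf["x", "Std. Error"]),
    p_slope = if (n >= 3) unname(cf["x", "Pr(>|t|)"]) else NA_real_,
    pearson_r = r,
    p_pearson = if (!is.null(ct)) ct$p.value else NA_real_,
    n = n,
    fit = fit,
    data = tibble(x = x, y = y)),
    class = "chromatography_regression")
}

#' @export
print.chromatography_regression <- function(x, ...) {
  cat(sprintf("<regression> slope = %.4g +/- %.3g (p = %.3g), intercept = %.4g, r = %.3f (p = %.3g), n = %d\n",
              x$slope, x$slope_se, x$p_slope, x$intercept, x$pearson_r,
              x$p_pearson, x$n))
  invisible(x)
}

#' @rdname linear_regression
#' @param x A `chromatography_regression`.
#' @param ... Unused.
#' @method tidy chromatography_regression
#' @export
tidy.chromatography_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(summary(x$fit)$coefficients["(Intercept)", "Std. Error"],
                       x$slope_se),
         p.value = c(summary(x$fit)$coefficients["(Intercept)", "Pr(>|t|)"],
                     x$p_slope))
}

#' @rdname linear_regression
#' @method glance chromatography_regression
#' @export
glance.chromatography_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
         p_slope = x$p_slope, pearson_r = x$pearson_r,
         p_pearson = x$p_pearson, n = x$n,
         r.squared = summary(x$fit)$r.squared)
}

#' @rdname linear_regression
#' @param object A `chromatography_regression`.
#' @method autoplot chromatography_regression
#' @export
autoplot.chromatography_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      subtitle = sprintf("slope = %.3g (p = %.3g), r = %.3f",
                         object$slope, object$p_slope, object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Tidy dose-response / shear-response table of run summaries
#'
#' Groups per-run experiment points (one [summarize_population()] summary per
#' independently run experiment) and reports mean, SEM and n of a chosen
#' metric per group — the tabular form downstream ANOVA or plotting consumes.
#' Groups with a single run have `sem = NA` and are flagged.
#'
#' @param points Tibble with one row per run: grouping columns (e.g.
#'   `heparin_dose`, `tau_wall`, `selectin_conc`, `cell_label`) and metric
#'   columns (e.g. `pct_rolling`, `mean_pct_binding_time`).
#' @param metric Metric column name (string).
#' @param group_by Character vector of grouping column names.
#' @return A tibble `group columns, n, mean, sem, single_run`, ordered by the
#'   grouping columns.
#' @export
dose_response_table <- function(points, metric, group_by) {
  if (!metric %in% names(points))
    stopf("unknown metric '%s'; available: %s", metric,
          paste(setdiff(names(points), group_by), collapse = ", "))
  miss <- setdiff(group_by, names(points))
  if (length(miss)) stopf("grouping columns not found: %s",
                          paste(miss, collapse = ", "))
  points |>
    group_by(across(all_of(group_by))) |>
    summarise(n = dplyr::n(),
              mean = mean(.data[[metric]], na.rm = TRUE),
              sem = if (dplyr::n() > 1)
                sd(.data[[metric]], na.rm = TRUE) / sqrt(dplyr::n())
              else NA_real_,
              .groups = "drop") |>
    mutate(single_run = .data$n == 1L) |>
    arrange(across(all_of(group_by)))
}
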