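#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a ranked decorrelated feature space
#'
#' One row per decorrelated component with its discrimination-power rank.
#'
#' @param x A `drf_space`.
#' @param ... Unused.
#' @return A tibble (component, rank_weight, raw_score, variance_rank).
#' @method tidy drf_space
#' @export
tidy.drf_space <- function(x, ...) {
  k <- ncol(x$transformed)
  out <- tibble::tibble(
    component = colnames(x$transformed),
    variance_rank = seq_len(k)
  )
  if (!is.null(x$rank_weight)) {
    out$rank_weight <- unname(x$rank_weight)
    out$raw_score <- unname(x$raw_score)
    out <- out[x$ordering, ]
  }
  out
}

#' @method glance drf_space
#' @export
glance.drf_space <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$transformed),
    n_features = length(x$feature_names),
    n_components = ncol(x$transformed),
    ranked = !is.null(x$rank_weight)
  )
}

#' Tidy / glance a discrimination result
#'
#' `tidy()` returns the top-feature signature; `glance()` the one-row
#' summary (index, overlap, chance p-value, distribution medians).
#'
#' @param x A `discrimination_result` from [discriminate()].
#' @param ... Unused.
#' @method tidy discrimination_result
#' @export
tidy.discrimination_result <- function(x, ...) {
  x$top_features
}

#' @rdname tidy.discrimination_result
#' @method glance discrimination_result
#' @export
glance.discrimination_result <- function(x, ...) {
  tibble::tibble(
    index = x$index,
    overlap = x$overlap,
    p_value = x$p_value,
    median_correct = median(x$correct_distribution$index),
    median_null = median(x$null_distribution$index),
    n_repetitions = x$cfg$n_repetitions
  )
}

#' Tidy / glance a penetrance result
#'
#' `tidy()` returns the per-subject mean absolute z-scores; `glance()` the
#' group-level summary and test p-values.
#'
#' @param x A `penetrance_result` from [penetrance_analysis()].
#' @param ... Unused.
#' @method tidy penetrance_result
#' @export
tidy.penetrance_result <- function(x, ...) {
  x$scores
}

#' @rdname tidy.penetrance_result
#' @method glance penetrance_result
#' @export
glance.penetrance_result <- function(x, ...) {
  tibble::tibble(
    z_WT = x$z_WT, z_MT = x$z_MT,
    sigma_WT = x$sigma_WT, sigma_MT = x$sigma_MT,
    mean_statistic = x$mean_test$statistic,
    mean_p = x$mean_test$p_value,
    variability_statistic = x$variability_test$statistic,
    variability_p = x$variability_test$p_value
  )
}

#' Tidy / glance gait fits
#'
#' `tidy()` gives coefficient rows in broom style (on the fitting scale:
#' log-log for power fits); `glance()` the fit summary including the
#' back-transformed power-law parameters.
#'
#' @param x A `power_fit` or `linear_fit`.
#' @param ... Unused.
#' @method tidy power_fit
#' @export
tidy.power_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("log_intercept", "exponent"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4]),
    conf.low = unname(x$conf_int[, 1]),
    conf.high = unname(x$conf_int[, 2])
  )
}

#' @rdname tidy.power_fit
#' @method glance power_fit
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, sigma = x$sigma,
                 r.squared = x$r.squared, n = x$n, group = x$group)
}

#' @rdname tidy.power_fit
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4]),
    conf.low = unname(x$conf_int[, 1]),
    conf.high = unname(x$conf_int[, 2])
  )
}

#' @rdname tidy.power_fit
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope, sigma = x$sigma,
                 r.squared = x$r.squared, n = x$n, group = x$group)
}

#' Tidy / glance a regression-line comparison
#'
#' `tidy()` gives one row per test (slope, elevation, combined);
#' `glance()` a one-row summary.
#'
#' @param x A `line_comparison` from [compare_regressions()].
#' @param ... Unused.
#' @method tidy line_comparison
#' @export
tidy.line_comparison <- function(x, ...) {
  tibble::tibble(
    term = c("slope_difference", "elevation_difference", "combined"),
    estimate = c(x$slope_difference, x$intercept_difference, NA_real_),
    statistic = c(NA_real_, NA_real_, x$f_statistic),
    p.value = c(x$slope_p, x$intercept_p, x$f_p)
  )
}

#' @rdname tidy.line_comparison
#' @method glance line_comparison
#' @export
glance.line_comparison <- function(x, ...) {
  tibble::tibble(
    slope_difference = x$slope_difference, slope_p = x$slope_p,
    intercept_difference = x$intercept_difference,
    intercept_p = x$intercept_p,
    f_statistic = x$f_statistic, f_p = x$f_p,
    transform = x$transform
  )
}
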