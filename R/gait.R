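#' Power-law fit of a gait feature against speed
#'
#' Fits `y = a * x^b` by ordinary least squares of `log(y)` on `log(x)`,
#' the standard way to adjust stride or stance durations for locomotor
#' speed before comparing genotypes. The back-transformed curve is exact
#' when the noise is multiplicative log-normal.
#'
#' @param data A data frame (e.g. a gait table).
#' @param x,y Columns (tidy-eval) holding the predictor and response;
#'   default `speed` and `stride_duration`. Both must be strictly
#'   positive.
#' @param group Optional single group label to record on the fit.
#' @return An object of class `power_fit`: `a` (scale), `b` (exponent),
#'   `log_intercept`, `sigma` (residual SD on the log scale),
#'   `r.squared`, `n`, `group`, and the underlying log-log `lm` fit.
#' @export
#' @examples
#' gt <- generate_gait_table(20, exponent_b = -0.4, seed = 2)
#' power_fit(dplyr::filter(gt, group == "WT"))
power_fit <- function(data, x = speed, y = stride_duration, group = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  check_positive(xv, yv)
  if (length(xv) < 3L) abort("need at least 3 observations")
  if (diff(range(xv)) == 0) abort("x is constant; no slope identifiable")
  fit <- lm(log(yv) ~ log(xv))
  s <- suppressWarnings(summary(fit))  # noiseless input is a legal case
  structure(
    list(
      a = exp(unname(coef(fit)[1])),
      b = unname(coef(fit)[2]),
      log_intercept = unname(coef(fit)[1]),
      sigma = s$sigma,
      r.squared = s$r.squared,
      n = length(xv),
      group = group %||% single_group_label(data),
      fit = fit,
      conf_int = suppressWarnings(confint(fit)),
      transform = "loglog"
    ),
    class = "power_fit"
  )
}

#' Linear fit of a gait feature against body weight
#'
#' Ordinary least squares of `y` on `x` with confidence intervals on slope
#' and intercept; used to adjust paw-image measures for body weight.
#'
#' @inheritParams power_fit
#' @return An object of class `linear_fit`: `intercept`, `slope`, `sigma`,
#'   `r.squared`, `n`, `group`, `conf_int`, and the underlying `lm`.
#' @export
linear_fit <- function(data, x = body_weight, y = paw_area, group = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (anyNA(xv) || anyNA(yv)) abort("missing values in regression inputs")
  if (length(xv) < 3L) abort("need at least 3 observations")
  if (diff(range(xv)) == 0) abort("x is constant; no slope identifiable")
  fit <- lm(yv ~ xv)
  s <- suppressWarnings(summary(fit))
  structure(
    list(
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      sigma = s$sigma,
      r.squared = s$r.squared,
      n = length(xv),
      group = group %||% single_group_label(data),
      fit = fit,
      conf_int = suppressWarnings(confint(fit)),
      transform = "identity"
    ),
    class = "linear_fit"
  )
}

check_positive <- function(xv, yv) {
  bad <- which(!is.finite(xv) | !is.finite(yv) | xv <= 0 | yv <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive or missing values in rows: %s",
                  paste(bad, collapse = ", ")))
  }
}

single_group_label <- function(data) {
  if (!"group" %in% names(data)) return(NA_character_)
  u <- unique(as.character(data$group))
  if (length(u) == 1L) u else NA_character_
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit%s> y = %.4g * x^%.4g  (R2 = %.3f, n = %d)\n",
              if (is.na(x$group)) "" else paste0(" ", x$group),
              x$a, x$b, x$r.squared, x$n))
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit%s> y = %.4g + %.4g * x  (R2 = %.3f, n = %d)\n",
              if (is.na(x$group)) "" else paste0(" ", x$group),
              x$intercept, x$slope, x$r.squared, x$n))
  invisible(x)
}

#' Compare regression lines between the two groups
#'
#' The standard interaction / elevation decomposition for asking whether a
#' genotype difference in a gait feature survives adjustment for speed or
#' body weight. On the chosen scale (log-log for power-law relations,
#' identity for linear ones) it fits `y ~ x * group` and tests: (1) slope
#' equality (the interaction coefficient); (2) elevation (intercept)
#' equality at a common slope, from `y ~ x + group`; and (3) the combined
#' two-degree-of-freedom F test of any group difference against the
#' single-line model. A leave-one-out range of each group's slope is
#' reported as an influence diagnostic, since such comparisons are easily
#' driven by extreme subjects.
#'
#' @param data A gait table containing both groups.
#' @param x,y Columns (tidy-eval); default `speed`, `stride_duration`.
#' @param transform `"loglog"` (default, power-law comparison) or
#'   `"identity"`.
#' @param loo Compute the leave-one-out slope diagnostic (default `TRUE`;
#'   disable in large simulations).
#' @return An object of class `line_comparison`: `slope_difference`,
#'   `slope_p`, `intercept_difference`, `intercept_p` (at common slope),
#'   `f_statistic`, `f_p` (combined test), `loo_slope_range` (tibble per
#'   group), group sizes, `transform` and the per-group fits.
#' @export
compare_regressions <- function(data, x = speed, y = stride_duration,
                                transform = c("loglog", "identity"),
                                loo = TRUE) {
  transform <- match.arg(transform)
  g <- check_groups(data, min_per_group = 3L)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) < 6L) abort("need at least 6 subjects in total")
  if (transform == "loglog") {
    check_positive(xv, yv)
    xv <- log(xv)
    yv <- log(yv)
  }
  df <- data.frame(x = xv, y = yv, g = g)

  fit_inter <- lm(y ~ x * g, data = df)
  fit_common <- lm(y ~ x + g, data = df)
  fit_single <- lm(y ~ x, data = df)

  s_inter <- suppressWarnings(summary(fit_inter))$coefficients
  s_common <- suppressWarnings(summary(fit_common))$coefficients
  an <- anova(fit_single, fit_inter)

  loo_tab <- NULL
  if (loo) {
    loo_tab <- df |>
      dplyr::group_by(.data$g) |>
      dplyr::group_modify(function(d, key) {
        slopes <- vapply(seq_len(nrow(d)), function(i) {
          unname(coef(lm(y ~ x, data = d[-i, ]))[2])
        }, numeric(1))
        tibble::tibble(slope_min = min(slopes), slope_max = max(slopes),
                       slope_range = diff(range(slopes)))
      }) |>
      dplyr::ungroup() |>
      dplyr::rename(group = "g")
  }

  structure(
    list(
      slope_difference = unname(s_inter[4, 1]),
      slope_p = unname(s_inter[4, 4]),
      intercept_difference = unname(s_common[3, 1]),
      intercept_p = unname(s_common[3, 4]),
      f_statistic = an$F[2],
      f_p = an$`Pr(>F)`[2],
      loo_slope_range = loo_tab,
      n = table(g),
      transform = transform,
      fits = lapply(split(df, df$g), function(d) {
        f <- lm(y ~ x, data = d)
        list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]))
      })
    ),
    class = "line_comparison"
  )
}

#' @export
print.line_comparison <- function(x, ...) {
  cat("<line_comparison> (", x$transform, " scale)\n", sep = "")
  cat(sprintf("  slope difference    %+.4g  (p = %.4g)\n",
              x$slope_difference, x$slope_p))
  cat(sprintf("  elevation difference %+.4g  (p = %.4g, common slope)\n",
              x$intercept_difference, x$intercept_p))
  cat(sprintf("  combined F = %.3f (p = %.4g)\n", x$f_statistic, x$f_p))
  invisible(x)
}
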