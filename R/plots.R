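#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_path geom_line
#'   geom_histogram geom_vline labs theme_minimal facet_wrap
#'   scale_color_manual scale_fill_manual after_stat geom_jitter
#'   geom_errorbar position_jitter
#' @export
ggplot2::autoplot

pheno_palette <- c(WT = "#2166ac", MUT = "#b2182b")

group_colors <- function(levels) {
  cols <- pheno_palette[levels]
  cols[is.na(cols)] <- c("#2166ac", "#b2182b")[seq_len(sum(is.na(cols)))]
  setNames(unname(cols), levels)
}

# Axis-aligned ellipse outline as a path, t in [0, 2pi).
ellipse_path <- function(cx, cy, rx, ry, n = 120L) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x = cx + rx * cos(t), y = cy + ry * sin(t))
}

#' Plot the drf-plane projection
#'
#' Scatter of subjects on the two top-ranked decorrelated features with,
#' per group, the mean (center point), the standard-error ellipse (small)
#' and the standard-deviation ellipse (large) — the standard view of how
#' well the two groups separate.
#'
#' @param object A `drf_projection` from [project_2d()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drf_projection
#' @export
autoplot.drf_projection <- function(object, ...) {
  ell <- object$ellipses |>
    tidyr::pivot_wider(names_from = "axis",
                       values_from = c("center", "sd_radius", "sem_radius"))
  paths <- ell |>
    dplyr::rowwise() |>
    dplyr::reframe(
      group = .data$group,
      dplyr::bind_rows(
        dplyr::mutate(ellipse_path(.data$center_drf1, .data$center_drf2,
                                   .data$sd_radius_drf1,
                                   .data$sd_radius_drf2),
                      which = "SD"),
        dplyr::mutate(ellipse_path(.data$center_drf1, .data$center_drf2,
                                   .data$sem_radius_drf1,
                                   .data$sem_radius_drf2),
                      which = "SEM")
      )
    )
  cols <- group_colors(levels(object$coords$group))
  ggplot(object$coords, aes(.data$drf1, .data$drf2,
                            color = .data$group)) +
    geom_point(size = 2) +
    geom_path(data = paths,
              aes(.data$x, .data$y, color = .data$group,
                  group = interaction(.data$group, .data$which)),
              linewidth = 0.4) +
    geom_point(data = ell,
               aes(.data$center_drf1, .data$center_drf2,
                   color = .data$group),
               shape = 3, size = 3, stroke = 1.2) +
    scale_color_manual(values = cols) +
    labs(x = object$components[1], y = object$components[2],
         color = "group") +
    theme_minimal()
}

#' Plot correct- vs randomized-label index distributions
#'
#' Overlaid histograms of the discrimination-index distributions obtained
#' with correct and randomized labels; their overlap estimates the chance
#' probability of the observed discrimination (vertical line).
#'
#' @param object A `discrimination_result` from [discriminate()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot discrimination_result
#' @export
autoplot.discrimination_result <- function(object, bins = 30L, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$correct_distribution, labels = "correct"),
    dplyr::mutate(object$null_distribution, labels = "randomized")
  )
  ggplot(d, aes(100 * .data$index, fill = .data$labels)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = bins,
                   alpha = 0.55, position = "identity") +
    geom_vline(xintercept = object$index, linetype = 2) +
    scale_fill_manual(values = c(correct = "#1b7837",
                                 randomized = "#2166ac")) +
    labs(x = "discrimination index (%)", y = "density", fill = "labels",
         title = sprintf("index %.1f%%, chance p = %.3g",
                         object$index, object$p_value)) +
    theme_minimal()
}

#' Plot per-subject penetrance scores
#'
#' Each subject's mean absolute z-score, by group, with the group mean and
#' one-SD whiskers; spread differences between the groups indicate
#' heterogeneous (incompletely penetrant) phenotypes.
#'
#' @param object A `penetrance_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot penetrance_result
#' @export
autoplot.penetrance_result <- function(object, ...) {
  sm <- tibble::tibble(
    group = factor(levels(object$scores$group),
                   levels = levels(object$scores$group)),
    z = c(object$z_WT, object$z_MT),
    s = c(object$sigma_WT, object$sigma_MT)
  )
  cols <- group_colors(levels(object$scores$group))
  ggplot(object$scores, aes(.data$group, .data$z_i,
                            color = .data$group)) +
    geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8) +
    geom_point(data = sm, aes(.data$group, .data$z), shape = 95,
               size = 10) +
    geom_errorbar(data = sm,
                  aes(.data$group, .data$z, ymin = .data$z - .data$s,
                      ymax = .data$z + .data$s),
                  inherit.aes = FALSE, width = 0.2) +
    scale_color_manual(values = cols, guide = "none") +
    labs(x = NULL, y = "mean |z| per subject") +
    theme_minimal()
}

#' Plot gait regressions by group
#'
#' Scatter of the gait table with per-group fitted curves: the power-law
#' stride-versus-speed relation (back-transformed from the log-log fit)
#' or the linear paw-area-versus-weight relation.
#'
#' @param data A gait table containing both groups.
#' @param x,y Columns (tidy-eval), e.g. `speed` and `stride_duration`.
#' @param transform `"loglog"` for a power-law fit, `"identity"` for
#'   linear.
#' @return A ggplot.
#' @export
plot_gait_fit <- function(data, x = speed, y = stride_duration,
                          transform = c("loglog", "identity")) {
  transform <- match.arg(transform)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  g <- as_group_factor(data$group)
  d <- tibble::tibble(x = xv, y = yv, group = g)
  curves <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(dd, key) {
      grid <- seq(min(dd$x), max(dd$x), length.out = 100)
      if (transform == "loglog") {
        f <- power_fit(dd, x = x, y = y)
        tibble::tibble(x = grid, y = f$a * grid^f$b)
      } else {
        f <- linear_fit(dd, x = x, y = y)
        tibble::tibble(x = grid, y = f$intercept + f$slope * grid)
      }
    }) |>
    dplyr::ungroup()
  cols <- group_colors(levels(g))
  ggplot(d, aes(.data$x, .data$y, color = .data$group)) +
    geom_point(size = 2, alpha = 0.8) +
    geom_line(data = curves, linewidth = 0.7) +
    scale_color_manual(values = cols) +
    labs(x = rlang::as_label(rlang::enquo(x)),
         y = rlang::as_label(rlang::enquo(y)), color = "group") +
    theme_minimal()
}
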