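#' Z-score features over the pooled cohort
#'
#' Centers and scales every feature column using the mean and SD taken over
#' all subjects of both groups together, so each retained feature has
#' pooled mean 0 and pooled SD 1. Zero-variance features cannot be scaled
#' and are dropped with a warning, never an error. Missing values are
#' ignored in the pooled moments and propagated.
#'
#' @param data A feature table: tibble with `subject_id`, `group` and
#'   numeric feature columns.
#' @return The table with feature columns standardized; dropped features
#'   are recorded in the `"dropped_features"` attribute.
#' @export
zscore_features <- function(data) {
  check_groups(data, min_per_group = 1L)
  fc <- feature_cols(data)
  if (!length(fc)) abort("no feature columns")
  m <- feature_matrix(data)
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2, sd, na.rm = TRUE)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    warn(sprintf("dropping %d zero-variance feature(s): %s",
                 sum(bad), paste(fc[bad], collapse = ", ")))
  }
  keep <- fc[!bad]
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  out <- dplyr::bind_cols(data[c("subject_id", "group")],
                          tibble::as_tibble(z))
  dom <- attr(data, "domains")
  if (!is.null(dom)) attr(out, "domains") <- dom[keep]
  attr(out, "dropped_features") <- fc[bad]
  out
}

#' Decorrelate features by pooled-covariance whitening
#'
#' Forms statistically independent (uncorrelated) linear combinations of
#' the z-scored features by principal-axis whitening of the pooled sample
#' covariance: the data are rotated onto the principal axes and each axis
#' is scaled to unit variance. Estimation is label-blind (both groups
#' pooled) so no group information leaks into the transform. The number of
#' retained components K is `min(max_components, rank of the data)` and is
#' capped at `n - 2` so downstream covariances stay estimable.
#'
#' @param data A z-scored feature table (see [zscore_features()]).
#' @param max_components Upper bound on K; defaults to `n - 2`.
#' @return An object of class `drf_space` with elements `loadings`
#'   (features x K, original features to whitened components),
#'   `transformed` (subjects x K, mutually uncorrelated columns),
#'   `center` (feature means removed), `subject_id`, `group`,
#'   `feature_names`, and (after [rank_features()]) `rank_weight` and
#'   `ordering`.
#' @export
decorrelate <- function(data, max_components = NULL) {
  check_groups(data, min_per_group = 1L)
  n <- nrow(data)
  if (n < 4L) abort("insufficient subjects (need at least 4)")
  m <- feature_matrix(data)
  if (anyNA(m)) {
    abort("decorrelation requires complete features; impute or drop first")
  }
  cap <- n - 2L
  max_components <- if (is.null(max_components)) cap
                    else min(check_count(max_components, "max_components"), cap)

  ctr <- colMeans(m)
  xc <- sweep(m, 2, ctr)
  sv <- svd(xc)
  # Rank from singular values: components with essentially zero variance
  # are rank deficiencies (e.g. duplicated features) and are collapsed.
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > max(tol, sqrt(.Machine$double.eps)))
  k <- min(max_components, rank)
  if (k < 1L) abort("data have rank zero after centering")

  sdev <- sv$d[seq_len(k)] / sqrt(n - 1)
  # Whitening: loadings map centered features to unit-variance scores.
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, sdev, "/")
  transformed <- sqrt(n - 1) * sv$u[, seq_len(k), drop = FALSE]
  colnames(transformed) <- paste0("drf", seq_len(k))
  dimnames(loadings) <- list(colnames(m), colnames(transformed))
  rownames(transformed) <- data$subject_id

  structure(
    list(
      loadings = loadings,
      transformed = transformed,
      center = ctr,
      subject_id = data$subject_id,
      group = as_group_factor(data$group),
      feature_names = colnames(m),
      rank_weight = NULL,
      ordering = NULL
    ),
    class = "drf_space"
  )
}

#' @export
print.drf_space <- function(x, ...) {
  cat("<drf_space> ", nrow(x$transformed), " subjects, ",
      length(x$feature_names), " features -> ", ncol(x$transformed),
      " decorrelated components\n", sep = "")
  if (!is.null(x$rank_weight)) {
    top <- x$ordering[seq_len(min(3L, length(x$ordering)))]
    cat("  ranked; top components: ",
        paste0(colnames(x$transformed)[top], " (",
               round(x$rank_weight[top], 1), "%)", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Rank decorrelated features by discrimination power
#'
#' Scores each decorrelated component by the absolute two-sample
#' standardized mean difference (Cohen's d with pooled SD) between the two
#' groups, then maps scores linearly to 0-100% with the most
#' discriminating component at 100. Ties are broken by lower component
#' index.
#'
#' @param space A `drf_space` from [decorrelate()].
#' @param groups Optional group labels; defaults to those stored in
#'   `space`.
#' @return `space` with `rank_weight` (0-100 per component), `raw_score`
#'   (|d|) and `ordering` (component indices, best first) filled in.
#' @export
rank_features <- function(space, groups = NULL) {
  stopifnot(inherits(space, "drf_space"))
  g <- as_group_factor(groups %||% space$group)
  if (nlevels(g) != 2L || any(table(g) < 3L)) {
    abort("ranking needs two groups with at least 3 subjects each")
  }
  score <- unname(apply(space$transformed, 2, cohens_d_abs, g = g))
  top <- max(score)
  space$raw_score <- score
  space$rank_weight <- if (top > 0) 100 * score / top else score * 0
  space$ordering <- order(-space$rank_weight)  # stable: ties by index
  space
}

# |Cohen's d| with pooled SD for a numeric vector split by a 2-level factor.
cohens_d_abs <- function(x, g) {
  xs <- split(x, g)
  n1 <- length(xs[[1]]); n2 <- length(xs[[2]])
  sp2 <- ((n1 - 1) * var(xs[[1]]) + (n2 - 1) * var(xs[[2]])) / (n1 + n2 - 2)
  if (sp2 <= 0) return(0)
  abs(mean(xs[[2]]) - mean(xs[[1]])) / sqrt(sp2)
}

#' Project subjects onto the two top-ranked decorrelated features
#'
#' Returns subject coordinates on the (drf1, drf2) plane spanned by the two
#' highest-ranked decorrelated features, together with per-group,
#' per-axis ellipse parameters: center (group mean), SD radius and SEM
#' radius (SD / sqrt(group n)) — the mean / standard-error / standard-
#' deviation ellipses used to visualize group separation.
#'
#' @param space A ranked `drf_space` (see [rank_features()]).
#' @param groups Optional group labels; defaults to those stored.
#' @return An object of class `drf_projection`: list with `coords` (tibble
#'   subject_id, group, drf1, drf2) and `ellipses` (tibble group, axis,
#'   center, sd_radius, sem_radius, n).
#' @export
project_2d <- function(space, groups = NULL) {
  stopifnot(inherits(space, "drf_space"))
  if (is.null(space$ordering)) space <- rank_features(space, groups)
  if (ncol(space$transformed) < 2L) {
    abort("need at least two decorrelated features")
  }
  g <- as_group_factor(groups %||% space$group)
  sel <- space$ordering[1:2]
  xy <- space$transformed[, sel, drop = FALSE]
  coords <- tibble::tibble(
    subject_id = space$subject_id,
    group = g,
    drf1 = xy[, 1],
    drf2 = xy[, 2]
  )
  ellipses <- coords |>
    tidyr::pivot_longer(c("drf1", "drf2"),
                        names_to = "axis", values_to = "value") |>
    dplyr::group_by(.data$group, .data$axis) |>
    dplyr::summarise(
      center = mean(.data$value),
      sd_radius = sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_radius = .data$sd_radius / sqrt(.data$n))
  structure(
    list(coords = coords, ellipses = ellipses,
         components = colnames(space$transformed)[sel],
         rank_weight = space$rank_weight[sel]),
    class = "drf_projection"
  )
}

#' @export
print.drf_projection <- function(x, ...) {
  cat("<drf_projection> ", nrow(x$coords), " subjects on plane (",
      paste(x$components, collapse = ", "), ")\n", sep = "")
  print(x$ellipses)
  invisible(x)
}
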