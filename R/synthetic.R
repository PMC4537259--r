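#' Specify a synthetic two-group cohort
#'
#' Builds and validates the parameter set for [generate_feature_table()].
#' The generator emulates the statistical structure a high-throughput
#' behavioral phenotyping run is assumed to produce: control subjects drawn
#' from a zero-mean, unit-variance Gaussian with block-equicorrelated
#' features; a standardized mean shift `effect_size` added on
#' `effect_features` for a fraction `penetrance_fraction` of mutants; and a
#' per-subject latent trait that correlates a subject's deviations across
#' all features with intensity `trait_rho`.
#'
#' @param n_control,n_mutant Subjects per group.
#' @param n_features Number of features F.
#' @param block_sizes Integer partition of `n_features` into blocks of
#'   mutually correlated features. Defaults to independent features.
#' @param within_block_rho Equicorrelation inside a block, in `[0, 1)`.
#' @param effect_features Indices (in `1:n_features`) carrying the group
#'   mean shift.
#' @param effect_size Standardized mean difference d, in units of the
#'   (unit) feature SD.
#' @param trait_rho Across-feature correlation of a subject's deviations,
#'   in `[0, 1]`. 1 makes each subject's deviation a pure trait (identical
#'   across features); 0 makes deviations independent states.
#' @param penetrance_fraction Proportion of mutants carrying the shift,
#'   in `(0, 1]`.
#' @param seed RNG seed; every draw is reproducible from it.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(n_control = 16, n_mutant = 16, n_features = 50,
#'             effect_features = 1:5, effect_size = 2, seed = 1)
cohort_spec <- function(n_control,
                        n_mutant,
                        n_features,
                        block_sizes = rep(1L, n_features),
                        within_block_rho = 0,
                        effect_features = integer(),
                        effect_size = 0,
                        trait_rho = 0,
                        penetrance_fraction = 1,
                        seed = 1L) {
  spec <- list(
    n_control = check_count(n_control, "n_control"),
    n_mutant = check_count(n_mutant, "n_mutant"),
    n_features = check_count(n_features, "n_features"),
    block_sizes = as.integer(block_sizes),
    within_block_rho = within_block_rho,
    effect_features = as.integer(effect_features),
    effect_size = effect_size,
    trait_rho = trait_rho,
    penetrance_fraction = penetrance_fraction,
    seed = as.integer(seed)
  )
  if (sum(spec$block_sizes) != spec$n_features) {
    abort("invalid spec: sum(block_sizes) must equal n_features")
  }
  if (any(spec$block_sizes < 1L)) {
    abort("invalid spec: block_sizes must be positive")
  }
  if (length(spec$effect_features) &&
      (min(spec$effect_features) < 1L ||
       max(spec$effect_features) > spec$n_features)) {
    abort("invalid spec: effect_features must lie in 1..n_features")
  }
  if (spec$within_block_rho < 0 || spec$within_block_rho >= 1) {
    abort("invalid spec: within_block_rho must be in [0, 1)")
  }
  if (spec$trait_rho < 0 || spec$trait_rho > 1) {
    abort("invalid spec: trait_rho must be in [0, 1]")
  }
  if (spec$penetrance_fraction <= 0 || spec$penetrance_fraction > 1) {
    abort("invalid spec: penetrance_fraction must be in (0, 1]")
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_control, " WT + ", x$n_mutant, " MUT, ",
      x$n_features, " features\n", sep = "")
  cat("  blocks: ", length(x$block_sizes), " (rho = ", x$within_block_rho,
      "), trait_rho = ", x$trait_rho, "\n", sep = "")
  cat("  effect: d = ", x$effect_size, " on ", length(x$effect_features),
      " features, penetrance = ", x$penetrance_fraction,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic feature table
#'
#' Draws a subjects-by-features table from the cohort model described in
#' [cohort_spec()]. Control features have mean 0 and unit marginal variance.
#' Within a block of size m the equicorrelation is `within_block_rho`; a
#' shared per-subject latent trait with loading `sqrt(trait_rho)` is mixed
#' in (features rescaled so marginal variance stays 1), making the
#' correlation between any two features in different blocks equal to
#' `trait_rho`. A fixed-size random subset of
#' `round(penetrance_fraction * n_mutant)` mutants (at least one) receives
#' `+effect_size` on `effect_features`.
#'
#' @param spec A [cohort_spec()].
#' @param feature_domains Optional character vector of length
#'   `n_features` tagging each feature with a domain (e.g. "gait",
#'   "speed"); stored in the `"domains"` attribute of the result.
#'
#' @return A tibble with columns `subject_id`, `group` (factor, levels
#'   `WT` then `MUT`) and one numeric column per feature (`f001`, ...).
#'   The ids of shift-carrying mutants are kept in the `"carriers"`
#'   attribute.
#' @export
generate_feature_table <- function(spec, feature_domains = NULL) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec")
  }
  n <- spec$n_control + spec$n_mutant
  f <- spec$n_features
  if (!is.null(feature_domains) && length(feature_domains) != f) {
    abort("feature_domains must have one tag per feature")
  }

  with_seed(spec$seed, {
    rho <- spec$within_block_rho
    tr <- spec$trait_rho
    # Block-equicorrelated noise: shared block factor + idiosyncratic part.
    block_id <- rep(seq_along(spec$block_sizes), spec$block_sizes)
    block_u <- matrix(rnorm(n * length(spec$block_sizes)), n)
    e <- sqrt(rho) * block_u[, block_id, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * f), n)
    # Latent trait: one scalar per subject loading on every feature.
    u <- rnorm(n)
    x <- sqrt(1 - tr) * e + sqrt(tr) * u

    group <- factor(rep(c("WT", "MUT"), c(spec$n_control, spec$n_mutant)),
                    levels = c("WT", "MUT"))
    carriers <- integer()
    if (length(spec$effect_features) && spec$effect_size != 0) {
      n_carry <- max(1L, round(spec$penetrance_fraction * spec$n_mutant))
      carriers <- spec$n_control +
        sort(sample.int(spec$n_mutant, n_carry))
      x[carriers, spec$effect_features] <-
        x[carriers, spec$effect_features] + spec$effect_size
    }

    fmt <- paste0("f%0", max(3L, nchar(f)), "d")
    colnames(x) <- sprintf(fmt, seq_len(f))
    ids <- sprintf("m%03d", seq_len(n))
    out <- tibble::tibble(subject_id = ids, group = group)
    out <- dplyr::bind_cols(out, tibble::as_tibble(x))
    if (!is.null(feature_domains)) {
      attr(out, "domains") <- setNames(as.character(feature_domains),
                                       colnames(x))
    }
    attr(out, "carriers") <- ids[carriers]
    out
  })
}

#' Generate a synthetic gait table
#'
#' Produces per-subject gait summaries obeying the allometric structure
#' gait analyses assume: stride duration follows a power law in locomotor
#' speed, `stride = a * speed^b * exp(e)` with log-normal noise
#' `e ~ N(0, noise_sd^2)` (so the log-log fit is exactly linear-Gaussian),
#' and paw image area is linear in body weight. Mutant speeds are shifted
#' by `group_speed_shift`.
#'
#' @param n_per_group Subjects per group.
#' @param exponent_b Power-law exponent b (typically negative: faster mice
#'   take shorter strides).
#' @param scale_a Power-law scale a (> 0), seconds at unit speed.
#' @param weight_slope Slope of paw area on body weight (area units per
#'   gram).
#' @param noise_sd SD of the multiplicative log-normal noise on durations
#'   and of the additive noise on paw area.
#' @param group_speed_shift Additive shift of mutant locomotor speed.
#' @param seed RNG seed.
#'
#' @return A tibble with `subject_id`, `group`, `speed`, `stride_duration`,
#'   `stance_duration`, `body_weight` (g) and `paw_area`.
#' @export
generate_gait_table <- function(n_per_group,
                                exponent_b = -0.4,
                                scale_a = 0.5,
                                weight_slope = 3,
                                noise_sd = 0.05,
                                group_speed_shift = 0,
                                seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 3L)
  if (scale_a <= 0) abort("`scale_a` must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")

  with_seed(seed, {
    n <- 2L * n_per_group
    group <- factor(rep(c("WT", "MUT"), each = n_per_group),
                    levels = c("WT", "MUT"))
    # Speeds on a plausible cm/s scale, log-normal so strictly positive.
    speed <- exp(rnorm(n, mean = log(15), sd = 0.25))
    speed[group == "MUT"] <- speed[group == "MUT"] + group_speed_shift
    if (any(speed <= 0)) {
      abort("group_speed_shift drove speeds non-positive")
    }
    stride <- scale_a * speed^exponent_b * exp(rnorm(n, 0, noise_sd))
    # Stance occupies roughly 60% of the stride cycle.
    stance <- 0.6 * stride * exp(rnorm(n, 0, noise_sd / 2))
    weight <- rnorm(n, mean = 25, sd = 2.5)
    weight <- pmax(weight, 12)
    paw <- 20 + weight_slope * weight + rnorm(n, 0, noise_sd * 20)
    tibble::tibble(
      subject_id = sprintf("m%03d", seq_len(n)),
      group = group,
      speed = speed,
      stride_duration = stride,
      stance_duration = stance,
      body_weight = weight,
      paw_area = paw
    )
  })
}
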