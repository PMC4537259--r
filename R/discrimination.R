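#' Construct a Gaussian cloud
#'
#' A cloud is the Gaussian approximation of one group of subjects in the
#' ranked decorrelated feature space: a mean vector, a covariance matrix
#' and the number of subjects it was fitted on.
#'
#' @param mean Numeric mean vector.
#' @param covariance Symmetric positive semi-definite matrix.
#' @param n Subjects used in the fit.
#' @return An object of class `gaussian_cloud`.
#' @export
gaussian_cloud <- function(mean, covariance, n = NA_integer_) {
  covariance <- as.matrix(covariance)
  if (length(mean) != nrow(covariance) ||
      nrow(covariance) != ncol(covariance)) {
    abort("mean and covariance dimensions disagree")
  }
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    abort("covariance must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort("covariance must be positive semi-definite")
  }
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 n = as.integer(n)),
            class = "gaussian_cloud")
}

#' @export
print.gaussian_cloud <- function(x, ...) {
  cat("<gaussian_cloud> dim ", length(x$mean), ", n = ", x$n, "\n", sep = "")
  cat("  mean:", signif(x$mean, 4), "\n")
  invisible(x)
}

#' Fit per-group Gaussian clouds
#'
#' Computes each group's sample mean and covariance on the top-ranked
#' plane (or on a projection's coordinates). Because group sizes are
#' small relative to the dimension, the covariance is shrunk toward its
#' diagonal with intensity `max(0, (K + 1) / n - 0.05)` (capped at 1) and
#' ridge-floored so its smallest eigenvalue is at least 1e-8.
#'
#' @param x A `drf_projection` from [project_2d()], a ranked `drf_space`,
#'   or a numeric matrix of coordinates.
#' @param groups Group labels (taken from `x` when it carries them).
#' @param dims Number of top-ranked dimensions to use when `x` is a
#'   `drf_space` (default 2, the drf plane).
#' @return A named list with one `gaussian_cloud` per group level.
#' @export
fit_clouds <- function(x, groups = NULL, dims = 2L) {
  if (inherits(x, "drf_projection")) {
    groups <- groups %||% x$coords$group
    m <- as.matrix(x$coords[c("drf1", "drf2")])
  } else if (inherits(x, "drf_space")) {
    if (is.null(x$ordering)) x <- rank_features(x, groups)
    groups <- groups %||% x$group
    dims <- min(dims, ncol(x$transformed))
    m <- x$transformed[, x$ordering[seq_len(dims)], drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  g <- as_group_factor(groups)
  if (nlevels(g) != 2L || any(table(g) < 3L)) {
    abort("cloud fitting needs two groups with at least 3 subjects each")
  }
  if (ncol(m) > min(table(g)) - 1L) {
    abort(paste0("dimension exceeds smallest group size - 1; ",
                 "reduce the number of dimensions"))
  }
  clouds <- lapply(split(seq_len(nrow(m)), g), function(idx) {
    fit_one_cloud(m[idx, , drop = FALSE])
  })
  clouds
}

fit_one_cloud <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  s <- cov(m)
  lambda <- min(1, max(0, (k + 1) / n - 0.05))
  sig <- (1 - lambda) * s + lambda * diag(diag(s), k)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    sig <- sig + diag(1e-8 - min(ev, 0) + 1e-10, k)
  }
  if (!all(is.finite(sig)) ||
      min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("singular covariance after shrinkage; reduce the dimension")
  }
  gaussian_cloud(colMeans(m), sig, n)
}

#' Resampling configuration
#'
#' Settings for the repeated subsample / randomized-label discrimination
#' runs and for Monte-Carlo overlap integration.
#'
#' @param n_repetitions Repetitions per distribution (>= 100, so that the
#'   chance p-value is supported by enough resamples).
#' @param subsample_fraction Fraction of each group drawn without
#'   replacement per repetition, in `(0, 1]`.
#' @param n_overlap_samples Monte-Carlo sample count for overlap
#'   integration in more than one dimension.
#' @param seed RNG seed controlling the whole resampling run.
#' @return An object of class `resample_config`.
#' @export
resample_config <- function(n_repetitions = 1000L,
                            subsample_fraction = 0.8,
                            n_overlap_samples = 1e5,
                            seed = 1L) {
  n_repetitions <- check_count(n_repetitions, "n_repetitions", min = 100L)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("`subsample_fraction` must be in (0, 1]")
  }
  n_overlap_samples <- check_count(n_overlap_samples, "n_overlap_samples",
                                   min = 10L)
  structure(list(n_repetitions = n_repetitions,
                 subsample_fraction = subsample_fraction,
                 n_overlap_samples = n_overlap_samples,
                 seed = as.integer(seed)),
            class = "resample_config")
}

#' Overlap coefficient of two Gaussian clouds
#'
#' The overlapping coefficient OVL is the integral of the pointwise
#' minimum of the two densities: 1 for identical distributions, 0 for
#' disjoint ones. Identical clouds return exactly 1. In one dimension with
#' equal variances the closed form `2 * pnorm(-|mu_a - mu_b| / (2 sigma))`
#' is used; other one-dimensional cases are integrated numerically. In
#' higher dimensions OVL is estimated by Monte-Carlo importance sampling
#' over the equal-weight mixture of the two clouds:
#' `mean(min(p_a, p_b) / p_mix)` at `cfg$n_overlap_samples` draws.
#'
#' @param a,b `gaussian_cloud` objects of the same dimension.
#' @param cfg A [resample_config()] (Monte-Carlo sample count and seed).
#' @return OVL in `[0, 1]`.
#' @export
cloud_overlap <- function(a, b, cfg = resample_config()) {
  stopifnot(inherits(a, "gaussian_cloud"), inherits(b, "gaussian_cloud"))
  if (length(a$mean) != length(b$mean)) {
    abort("clouds have different dimensions")
  }
  if (isTRUE(all.equal(a$mean, b$mean, tolerance = 1e-12)) &&
      isTRUE(all.equal(a$covariance, b$covariance, tolerance = 1e-12))) {
    return(1)
  }
  if (length(a$mean) == 1L) {
    return(overlap_1d(a$mean, sqrt(a$covariance[1]),
                      b$mean, sqrt(b$covariance[1])))
  }
  with_seed(cfg$seed, overlap_mc(a, b, cfg$n_overlap_samples))
}

overlap_1d <- function(mu_a, sd_a, mu_b, sd_b) {
  if (abs(sd_a - sd_b) < 1e-9 * max(sd_a, sd_b)) {
    return(2 * pnorm(-abs(mu_a - mu_b) / (2 * sd_a)))
  }
  f <- function(x) pmin(dnorm(x, mu_a, sd_a), dnorm(x, mu_b, sd_b))
  lo <- min(mu_a - 10 * sd_a, mu_b - 10 * sd_b)
  hi <- max(mu_a + 10 * sd_a, mu_b + 10 * sd_b)
  v <- stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-12)$value
  min(max(v, 0), 1)
}

overlap_mc <- function(a, b, n_samples) {
  na <- ceiling(n_samples / 2)
  nb <- n_samples - na
  k <- length(a$mean)
  x <- rbind(matrix(MASS::mvrnorm(na, a$mean, a$covariance), ncol = k),
             matrix(MASS::mvrnorm(nb, b$mean, b$covariance), ncol = k))
  la <- dmvnorm_log(x, a$mean, a$covariance)
  lb <- dmvnorm_log(x, b$mean, b$covariance)
  lmin <- pmin(la, lb)
  lmax <- pmax(la, lb)
  lmix <- lmax + log1p(exp(lmin - lmax)) - log(2)  # log of the mixture
  v <- mean(exp(lmin - lmix))
  min(max(v, 0), 1)
}

#' Discrimination index of two Gaussian clouds
#'
#' The discrimination probability, `1 - OVL`: zero for identical clouds
#' (chance level, 100% overlap) and 1 for error-free discrimination of
#' fully separated clouds. Conventionally reported as a percentage.
#'
#' @inheritParams cloud_overlap
#' @param as_percent Return on the 0-100 scale (default) or 0-1.
#' @return The index.
#' @export
discrimination_index <- function(a, b, cfg = resample_config(),
                                 as_percent = TRUE) {
  idx <- 1 - cloud_overlap(a, b, cfg)
  if (as_percent) 100 * idx else idx
}

# One full pipeline pass on a plain matrix: z-score -> whiten -> rank ->
# top-2 clouds -> 1 - overlap (0-1 scale). Used inside the resampling loop,
# where tibble plumbing would dominate the run time. Consumes RNG for the
# Monte-Carlo overlap draw.
index_once <- function(m, g, n_mc) {
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- (colSums(m^2) - n * mu^2) / (n - 1)
  keep <- which(is.finite(s2) & s2 > 0)
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2,
             sqrt(s2[keep]), "/")
  # Whitening through the n x n Gram matrix (n << F inside the loop).
  ev <- eigen(tcrossprod(z), symmetric = TRUE)
  pos <- ev$values > max(ev$values[1] * 1e-12, .Machine$double.eps)
  k <- min(n - 2L, sum(pos))
  tx <- sqrt(n - 1) * ev$vectors[, seq_len(k), drop = FALSE]
  i2 <- g == levels(g)[2]
  n1 <- sum(!i2); n2 <- sum(i2)
  m1 <- colMeans(tx[!i2, , drop = FALSE])
  m2 <- colMeans(tx[i2, , drop = FALSE])
  v1 <- (colSums(tx[!i2, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(tx[i2, , drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d_abs <- ifelse(sp2 > 0, abs(m2 - m1) / sqrt(sp2), 0)
  sel <- order(-d_abs)[seq_len(min(2L, k))]
  a <- fit_one_cloud(tx[!i2, sel, drop = FALSE])
  b <- fit_one_cloud(tx[i2, sel, drop = FALSE])
  1 - overlap_mc(a, b, n_mc)
}

#' Repeated subsampled discrimination
#'
#' Runs the full pipeline (z-score, decorrelate, rank, fit top-2 clouds,
#' index) on many random subsamples of the cohort, optionally after
#' permuting the group labels, and returns the resulting distribution of
#' discrimination indexes. Re-ranking happens inside every repetition so
#' that feature selection optimism is reflected in the randomized-label
#' null rather than inflating the correct-label distribution only.
#'
#' @param data A feature table.
#' @param cfg A [resample_config()].
#' @param randomize_labels Permute group labels before each repetition
#'   (the chance null).
#' @return A tibble with columns `rep` and `index` (0-1 scale),
#'   `cfg$n_repetitions` rows; deterministic given `cfg$seed`.
#' @export
repeated_discrimination <- function(data, cfg = resample_config(),
                                    randomize_labels = FALSE) {
  g <- check_groups(data)
  stopifnot(inherits(cfg, "resample_config"))
  m <- feature_matrix(data)
  if (anyNA(m)) abort("resampling requires complete features")
  n_by_g <- table(g)
  n_sub <- ceiling(cfg$subsample_fraction * n_by_g)
  if (any(n_sub < 3L)) {
    abort(paste0("subsampling would leave a group with fewer than 3 ",
                 "subjects; increase group sizes or subsample_fraction"))
  }
  g_idx <- split(seq_len(nrow(m)), g)
  seed_offset <- if (randomize_labels) 1L else 0L
  idx <- with_seed(cfg$seed + seed_offset, {
    vapply(seq_len(cfg$n_repetitions), function(r) {
      gg <- if (randomize_labels) sample(g) else g
      gi <- split(seq_len(nrow(m)), gg)
      take <- c(gi[[1]][sample.int(length(gi[[1]]), n_sub[1])],
                gi[[2]][sample.int(length(gi[[2]]), n_sub[2])])
      index_once(m[take, , drop = FALSE], gg[take], cfg$n_overlap_samples)
    }, numeric(1))
  })
  tibble::tibble(rep = seq_along(idx), index = idx)
}

#' Chance p-value from correct- and randomized-label index distributions
#'
#' The probability that the observed discrimination arises by chance is
#' estimated as the overlap between the correct-label and
#' randomized-label index distributions, computed as
#' `sum(min(prop_correct, prop_null))` on a shared histogram with
#' Freedman-Diaconis bin widths derived from the pooled sample.
#'
#' @param correct,null Index distributions (numeric vectors or tibbles
#'   from [repeated_discrimination()]).
#' @return p in `[0, 1]`: 1 when the distributions coincide, 0 when their
#'   supports are disjoint.
#' @export
chance_p_value <- function(correct, null) {
  correct <- as_index_vector(correct)
  null <- as_index_vector(null)
  if (!length(correct) || !length(null)) {
    abort("both index distributions must be non-empty")
  }
  pooled <- c(correct, null)
  h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  if (!is.finite(h) || h <= 0) {
    h <- diff(range(pooled)) / stats::nclass.Sturges(pooled)
  }
  if (!is.finite(h) || h <= 0) {
    return(1)  # all values identical in both distributions
  }
  lo <- min(pooled) - h / 2
  breaks <- seq(lo, max(pooled) + h, by = h)
  pc <- tabulate(findInterval(correct, breaks), length(breaks)) /
    length(correct)
  pn <- tabulate(findInterval(null, breaks), length(breaks)) / length(null)
  min(max(sum(pmin(pc, pn)), 0), 1)
}

as_index_vector <- function(x) {
  if (is.data.frame(x)) x <- x$index
  as.numeric(x)
}

#' Top contributing original features
#'
#' Identifies the original features most loaded on the highly ranked
#' decorrelated components (loading = |correlation| between the feature
#' and each component, weighted by the component's rank) and reports each
#' feature's relative normalized difference between groups,
#' `100 * (mean_MUT - mean_WT) / (|mean_WT| + |mean_MUT| + eps)`, together
#' with a 0-100% feature rank.
#'
#' @param data The raw (un-scaled) feature table the space was built from.
#' @param space A ranked `drf_space`.
#' @param n_top How many features to report.
#' @return A tibble (feature, rank_weight, relative_difference, mean_WT,
#'   mean_MUT), best-ranked first.
#' @export
top_features <- function(data, space, n_top = 10L) {
  stopifnot(inherits(space, "drf_space"))
  if (is.null(space$rank_weight)) abort("rank the space first")
  feats <- space$feature_names
  if (n_top > length(feats)) {
    warn(sprintf("n_top truncated to the %d available features",
                 length(feats)))
    n_top <- length(feats)
  }
  m <- feature_matrix(data)[, feats, drop = FALSE]
  g <- as_group_factor(data$group)
  load_cor <- abs(suppressWarnings(cor(m, space$transformed)))
  load_cor[!is.finite(load_cor)] <- 0
  score <- drop(load_cor %*% (space$rank_weight / 100))
  weight <- if (max(score) > 0) 100 * score / max(score) else score
  mw <- colMeans(m[g == levels(g)[1], , drop = FALSE], na.rm = TRUE)
  mm <- colMeans(m[g == levels(g)[2], , drop = FALSE], na.rm = TRUE)
  rel <- 100 * (mm - mw) / (abs(mw) + abs(mm) + 1e-12)
  ord <- order(-weight)[seq_len(n_top)]
  tibble::tibble(
    feature = feats[ord],
    rank_weight = unname(weight[ord]),
    relative_difference = unname(rel[ord]),
    mean_WT = unname(mw[ord]),
    mean_MUT = unname(mm[ord])
  )
}

#' Full discrimination analysis of a feature table
#'
#' The end-to-end pipeline: pooled z-scoring, whitening decorrelation,
#' discrimination-power ranking, Gaussian clouds on the top-2 plane and
#' their overlap-based discrimination index; then repeated subsampling
#' with correct and randomized labels to build the index distributions
#' whose overlap gives the chance p-value; and the top-feature signature.
#'
#' @param data A feature table (tibble: `subject_id`, `group`, features).
#' @param cfg A [resample_config()].
#' @param n_top Number of top features to report.
#' @return An object of class `discrimination_result` with fields
#'   `index` (percent), `overlap`, `p_value`, `correct_distribution`,
#'   `null_distribution`, `top_features`, `projection`, `clouds`, `cfg`.
#' @export
#' @examples
#' spec <- cohort_spec(16, 16, 40, effect_features = 1:8,
#'                     effect_size = 2.5, seed = 7)
#' tab <- generate_feature_table(spec)
#' res <- discriminate(tab, resample_config(n_repetitions = 100,
#'                                          n_overlap_samples = 2000,
#'                                          seed = 7))
#' glance(res)
discriminate <- function(data, cfg = resample_config(), n_top = 10L) {
  check_groups(data)
  space <- data |>
    zscore_features() |>
    decorrelate() |>
    rank_features()
  proj <- project_2d(space)
  clouds <- fit_clouds(proj)
  ovl <- cloud_overlap(clouds[[1]], clouds[[2]], cfg)
  correct <- repeated_discrimination(data, cfg, randomize_labels = FALSE)
  null <- repeated_discrimination(data, cfg, randomize_labels = TRUE)
  structure(
    list(
      index = 100 * (1 - ovl),
      overlap = ovl,
      p_value = chance_p_value(correct, null),
      correct_distribution = correct,
      null_distribution = null,
      top_features = top_features(data, space, n_top),
      space = space,
      projection = proj,
      clouds = clouds,
      cfg = cfg
    ),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> index %.1f%% (overlap %.3f), p = %.4g\n",
              x$index, x$overlap, x$p_value))
  cat(sprintf("  %d repetitions per label condition\n",
              x$cfg$n_repetitions))
  invisible(x)
}

#' Per-domain discrimination
#'
#' Runs the full discrimination pipeline independently on each domain's
#' feature subset and on all features combined, producing the
#' domain-by-index grid used to localize which behavioral domains drive a
#' separation.
#'
#' @param data A feature table.
#' @param domains Named character vector mapping feature name to domain
#'   tag; defaults to the table's `"domains"` attribute.
#' @param cfg A [resample_config()].
#' @param alpha Significance threshold for flagging a domain.
#' @return A tibble (domain, n_features, index, p_value, significant) with
#'   the full `discrimination_result` objects in a `result` list-column.
#' @export
domain_discrimination <- function(data, domains = NULL,
                                  cfg = resample_config(), alpha = 0.05) {
  domains <- domains %||% attr(data, "domains")
  if (is.null(domains)) abort("no feature domains available")
  fc <- feature_cols(data)
  domains <- domains[intersect(names(domains), fc)]
  groups_list <- c(list(`all features` = names(domains)),
                   split(names(domains), domains))
  rows <- purrr::imap(groups_list, function(feats, dom) {
    if (length(feats) < 2L) {
      warn(sprintf("domain '%s' has fewer than 2 features; skipped", dom))
      return(NULL)
    }
    sub <- data[c("subject_id", "group", feats)]
    res <- discriminate(sub, cfg, n_top = min(10L, length(feats)))
    tibble::tibble(domain = dom, n_features = length(feats),
                   index = res$index, p_value = res$p_value,
                   significant = res$p_value < alpha,
                   result = list(res))
  })
  dplyr::bind_rows(rows)
}
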