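#' Per-subject penetrance z-score analysis
#'
#' Quantifies how extreme each subject is across the whole feature set.
#' Every feature is z-scored over the pooled cohort (both groups
#' together), and each subject's penetrance statistic is the mean absolute
#' z-score across features, `z_i = (1/F) sum_f |z_{f,i}|`. If mutants are
#' consistently extreme, the mutant group mean `z_MT` exceeds the control
#' mean `z_WT`; if only some mutants are extreme (incomplete penetrance)
#' the mutant variability `sigma_MT` also exceeds `sigma_WT`. Group mean
#' and variability are compared with permutation tests: the mean test
#' permutes labels and recomputes the difference of group means of `z_i`;
#' the variability test is Levene-type, permuting labels and recomputing
#' the difference of group means of `|z_i - group median|`.
#'
#' Missing feature values are allowed: a subject's `z_i` averages its
#' non-missing features, and subjects missing more than half of the
#' features are excluded with a warning.
#'
#' @param data A feature table (tibble: `subject_id`, `group`, features).
#' @param n_permutations Label permutations for both tests.
#' @param alternative Direction for both tests, mutant relative to
#'   control: `"two.sided"` (default), `"greater"` or `"less"`.
#' @param seed RNG seed for the permutations.
#' @return An object of class `penetrance_result`: `scores` (tibble
#'   subject_id, group, z_i, n_features_used), `z_matrix`, group summaries
#'   `z_WT`, `z_MT`, `sigma_WT`, `sigma_MT`, and `mean_test` /
#'   `variability_test` (each: statistic = MUT minus WT, p_value,
#'   n_permutations).
#' @export
#' @examples
#' tab <- generate_feature_table(
#'   cohort_spec(12, 12, 30, effect_features = 1:30, effect_size = 1.5,
#'               penetrance_fraction = 0.5, trait_rho = 1, seed = 3))
#' pen <- penetrance_analysis(tab, n_permutations = 500)
#' glance(pen)
penetrance_analysis <- function(data, n_permutations = 10000L,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                seed = 1L) {
  alternative <- match.arg(alternative)
  g <- check_groups(data)
  n_permutations <- check_count(n_permutations, "n_permutations",
                                min = 100L)
  z_tab <- zscore_features(data)
  if (length(feature_cols(z_tab)) < 2L) {
    abort("need at least 2 features with nonzero variance")
  }
  z <- feature_matrix(z_tab)

  n_ok <- as.integer(rowSums(!is.na(z)))
  too_missing <- n_ok < ncol(z) / 2
  if (any(too_missing)) {
    warn(sprintf("excluding %d subject(s) missing > 50%% of features: %s",
                 sum(too_missing),
                 paste(data$subject_id[too_missing], collapse = ", ")))
    z <- z[!too_missing, , drop = FALSE]
    g <- droplevels(g[!too_missing])
    n_ok <- n_ok[!too_missing]
    if (nlevels(g) != 2L || any(table(g) < 3L)) {
      abort("fewer than 3 usable subjects in a group")
    }
  }
  z_i <- rowMeans(abs(z), na.rm = TRUE)

  is_mut <- g == levels(g)[2]
  grp_mean <- tapply(z_i, g, mean)
  grp_sd <- tapply(z_i, g, sd)

  tests <- with_seed(seed, list(
    mean = permutation_test(z_i, is_mut, mean_diff_stat,
                            n_permutations, alternative),
    variability = permutation_test(z_i, is_mut, levene_stat,
                                   n_permutations, alternative)
  ))

  structure(
    list(
      scores = tibble::tibble(
        subject_id = rownames(z),
        group = g,
        z_i = unname(z_i),
        n_features_used = unname(n_ok)
      ),
      z_matrix = z,
      z_WT = unname(grp_mean[1]), z_MT = unname(grp_mean[2]),
      sigma_WT = unname(grp_sd[1]), sigma_MT = unname(grp_sd[2]),
      mean_test = tests$mean,
      variability_test = tests$variability,
      alternative = alternative
    ),
    class = "penetrance_result"
  )
}

# MUT mean minus WT mean of the per-subject statistic.
mean_diff_stat <- function(x, is_mut) {
  mean(x[is_mut]) - mean(x[!is_mut])
}

# Brown-Forsythe-type spread statistic: group means of absolute deviations
# from the own-group median, MUT minus WT.
levene_stat <- function(x, is_mut) {
  d_mut <- abs(x[is_mut] - median(x[is_mut]))
  d_wt <- abs(x[!is_mut] - median(x[!is_mut]))
  mean(d_mut) - mean(d_wt)
}

permutation_test <- function(x, is_mut, stat_fun, n_perm, alternative) {
  obs <- stat_fun(x, is_mut)
  n <- length(x)
  perm <- vapply(seq_len(n_perm), function(b) {
    stat_fun(x, is_mut[sample.int(n)])
  }, numeric(1))
  p <- switch(alternative,
    two.sided = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
    greater = (1 + sum(perm >= obs)) / (1 + n_perm),
    less = (1 + sum(perm <= obs)) / (1 + n_perm)
  )
  list(statistic = obs, p_value = p, n_permutations = n_perm,
       alternative = alternative)
}

#' @export
print.penetrance_result <- function(x, ...) {
  cat("<penetrance_result> ", nrow(x$scores), " subjects, ",
      ncol(x$z_matrix), " features\n", sep = "")
  cat(sprintf("  z_WT = %.3f (sigma %.3f), z_MT = %.3f (sigma %.3f)\n",
              x$z_WT, x$sigma_WT, x$z_MT, x$sigma_MT))
  cat(sprintf("  mean test p = %.4g, variability test p = %.4g (%s)\n",
              x$mean_test$p_value, x$variability_test$p_value,
              x$alternative))
  invisible(x)
}

#' Trait-versus-state contrast of the penetrance statistic
#'
#' Summarizes how variable the per-subject mean absolute z-score is,
#' relative to the per-feature variability of |z|. When a subject's
#' deviations are perfectly correlated across features (a trait), the SD
#' of `z_i` across subjects approaches the per-feature SD of |z|
#' (`sqrt(1 - 2/pi) ~ 0.603` for standard normal features); when
#' deviations are independent per feature (a state), it shrinks at the
#' `1/sqrt(F)` rate.
#'
#' @param data A feature table.
#' @return A one-row tibble: `sd_z_i` (SD across subjects of the mean
#'   absolute z), `mean_feature_sd` (per-feature SD of |z|, averaged over
#'   features), `n_features`, and their ratio `shrinkage` =
#'   `sd_z_i / mean_feature_sd`.
#' @export
trait_state_contrast <- function(data) {
  check_groups(data)
  z <- feature_matrix(zscore_features(data))
  z_i <- rowMeans(abs(z), na.rm = TRUE)
  per_feature_sd <- apply(abs(z), 2, sd, na.rm = TRUE)
  tibble::tibble(
    sd_z_i = sd(z_i),
    mean_feature_sd = mean(per_feature_sd),
    n_features = ncol(z),
    shrinkage = sd(z_i) / mean(per_feature_sd)
  )
}
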