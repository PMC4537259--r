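# Shared fixtures: small cohorts and a fast resampling configuration.

quick_cfg <- function(seed = 1L, reps = 100L, mc = 500L) {
  resample_config(n_repetitions = reps, n_overlap_samples = mc, seed = seed)
}

null_cohort <- function(seed = 1L, n = 16L, f = 200L) {
  generate_feature_table(cohort_spec(n, n, f, seed = seed))
}

effect_cohort <- function(seed = 1L, n = 16L, f = 200L, d = 3,
                          n_effect = 20L, ...) {
  generate_feature_table(cohort_spec(n, n, f,
                                     effect_features = seq_len(n_effect),
                                     effect_size = d, seed = seed, ...))
}

# Minimal hand-built ranked space: components with prescribed group
# standardized differences, for testing ranking/projection in isolation.
toy_space <- function(score_per_component, n_per_group = 16L, seed = 99L) {
  k <- length(score_per_component)
  withr::with_seed(seed, {
    g <- factor(rep(c("WT", "MUT"), each = n_per_group),
                levels = c("WT", "MUT"))
    tx <- sapply(score_per_component, function(d) {
      x <- rnorm(2 * n_per_group)
      x[g == "MUT"] <- x[g == "MUT"] + d
      x
    })
    colnames(tx) <- paste0("drf", seq_len(k))
    structure(
      list(loadings = diag(k), transformed = tx, center = rep(0, k),
           subject_id = sprintf("m%03d", seq_len(2 * n_per_group)),
           group = g, feature_names = paste0("f", seq_len(k)),
           rank_weight = NULL, ordering = NULL),
      class = "drf_space"
    )
  })
}
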