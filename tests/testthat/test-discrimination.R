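test_that("overlap matches the closed form and its analytic limits", {
  cfg <- quick_cfg(seed = 1, mc = 100000L)
  # identical clouds: 100% overlap, zero discrimination
  cl <- gaussian_cloud(c(0.3, -1), matrix(c(1, 0.4, 0.4, 2), 2), n = 10)
  expect_identical(cloud_overlap(cl, cl, cfg), 1)
  expect_identical(discrimination_index(cl, cl, cfg), 0)

  # 1D equal variance, means 0 and 2: OVL = 2 * pnorm(-1)
  a <- gaussian_cloud(0, matrix(1), 10)
  b <- gaussian_cloud(2, matrix(1), 10)
  expect_equal(cloud_overlap(a, b, cfg), 2 * pnorm(-1), tolerance = 1e-9)
  expect_equal(discrimination_index(a, b, cfg, as_percent = FALSE),
               1 - 2 * pnorm(-1), tolerance = 1e-9)

  # independent oracle: numeric grid integration of min of the densities
  grid <- seq(-8, 10, by = 1e-4)
  ovl_grid <- sum(pmin(dnorm(grid, 0, 1), dnorm(grid, 2, 1))) * 1e-4
  expect_equal(cloud_overlap(a, b, cfg), ovl_grid, tolerance = 1e-4)

  # essentially disjoint clouds
  far <- gaussian_cloud(1e6, matrix(1), 10)
  expect_equal(cloud_overlap(a, far, cfg), 0)
  expect_equal(discrimination_index(a, far, cfg), 100)

  # unequal variances: numeric path against a grid oracle
  c2 <- gaussian_cloud(1, matrix(4), 10)
  ovl_grid2 <- sum(pmin(dnorm(grid, 0, 1), dnorm(grid, 1, 2))) * 1e-4
  expect_equal(cloud_overlap(a, c2, cfg), ovl_grid2, tolerance = 1e-4)

  expect_error(cloud_overlap(cl, a, cfg), "dimension")
})

test_that("Monte-Carlo overlap in 2D tracks the 1D closed form", {
  # two spherical 2D clouds separated along one axis reduce to the 1D case
  cfg <- quick_cfg(seed = 2, mc = 100000L)
  for (d in c(0.5, 1, 2)) {
    a <- gaussian_cloud(c(0, 0), diag(2), 10)
    b <- gaussian_cloud(c(d, 0), diag(2), 10)
    expect_lt(abs(cloud_overlap(a, b, cfg) - 2 * pnorm(-d / 2)), 0.01)
  }
})

test_that("index grows with the Mahalanobis separation of the means", {
  cfg <- quick_cfg(seed = 3, mc = 50000L)
  idx <- vapply(c(0.5, 1, 2, 3, 4), function(d) {
    discrimination_index(gaussian_cloud(c(0, 0), diag(2), 10),
                         gaussian_cloud(c(d, 0), diag(2), 10), cfg,
                         as_percent = FALSE)
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
  expect_true(all(idx >= 0 & idx <= 1))
})

test_that("cloud fitting is consistent, shrunk, and deterministic", {
  mu <- c(1, -2)
  sig <- matrix(c(2, 0.8, 0.8, 1), 2)
  x <- withr::with_seed(4, MASS::mvrnorm(4000, mu, sig))
  g <- factor(rep(c("WT", "MUT"), each = 2000), levels = c("WT", "MUT"))
  cl <- fit_clouds(x, g)
  expect_equal(cl$WT$mean, mu, tolerance = 0.1)
  expect_equal(cl$MUT$covariance, sig, tolerance = 0.12)

  # n = 3 per group in 2D: shrinkage keeps the covariance usable
  x3 <- withr::with_seed(5, matrix(rnorm(12), 6, 2))
  g3 <- factor(rep(c("WT", "MUT"), each = 3), levels = c("WT", "MUT"))
  cl3 <- fit_clouds(x3, g3)
  ev <- eigen(cl3$WT$covariance, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  # identical subject sets give identical clouds
  xx <- rbind(x3[1:3, ], x3[1:3, ])
  cl_same <- fit_clouds(xx, g3)
  expect_equal(cl_same$WT, cl_same$MUT)

  # dimension above min group size - 1 is refused
  expect_error(fit_clouds(withr::with_seed(8, matrix(rnorm(18), 6, 3)), g3),
               "reduce the number of dimensions")
})

test_that("repeated discrimination is seed-deterministic and separates signal", {
  tab <- effect_cohort(seed = 31, d = 4, n_effect = 40)
  cfg <- quick_cfg(seed = 31)
  d1 <- repeated_discrimination(tab, cfg)
  d2 <- repeated_discrimination(tab, cfg)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 100L)
  # large planted effect: correct-label indexes concentrate near 100%
  expect_gt(median(d1$index), 0.95)

  null_d <- repeated_discrimination(tab, cfg, randomize_labels = TRUE)
  expect_lt(median(null_d$index), median(d1$index))

  tiny <- null_cohort(seed = 1, n = 3, f = 10)
  small_cfg <- resample_config(n_repetitions = 100,
                               subsample_fraction = 0.5, seed = 1)
  expect_error(repeated_discrimination(tiny, small_cfg),
               "subsample_fraction")
})

test_that("the randomized-label optimism shrinks as cohorts grow", {
  means <- vapply(c(8L, 32L), function(n) {
    tab <- null_cohort(seed = 32, n = n, f = 100)
    mean(repeated_discrimination(tab, quick_cfg(seed = n, mc = 300L),
                                 randomize_labels = TRUE)$index)
  }, numeric(1))
  expect_gt(means[1], 0)
  expect_lt(means[2], means[1])
})

test_that("chance p-value behaves as a distribution overlap", {
  x <- withr::with_seed(6, runif(500))
  expect_identical(chance_p_value(x, x), 1)
  expect_identical(chance_p_value(x, x + 10), 0)
  y <- withr::with_seed(7, runif(500))
  p <- chance_p_value(x, y)
  expect_gt(p, 0.5)  # same distribution, sampling noise only
  expect_error(chance_p_value(numeric(), x), "non-empty")
})

test_that("chance p-value is stochastically large on null cohorts", {
  ps <- vapply(1:12, function(i) {
    tab <- null_cohort(seed = 700 + i, n = 12, f = 80)
    cfg <- quick_cfg(seed = i, mc = 300L)
    chance_p_value(repeated_discrimination(tab, cfg),
                   repeated_discrimination(tab, cfg, TRUE))
  }, numeric(1))
  expect_gt(median(ps), 0.3)
})

test_that("top features report rank and relative normalized difference", {
  tab <- effect_cohort(seed = 33, n = 16, f = 50, d = 3, n_effect = 5)
  sp <- rank_features(decorrelate(zscore_features(tab)))
  tf <- top_features(tab, sp, n_top = 5)
  expect_identical(nrow(tf), 5L)
  expect_true(all(tf$feature %in% sprintf("f%03d", 1:5)))
  expect_true(all(diff(tf$rank_weight) <= 0))

  # definition cases on a hand-built table
  toy <- tibble::tibble(
    subject_id = sprintf("s%d", 1:12),
    group = rep(c("WT", "MUT"), each = 6),
    same = rep(c(1, 2, 3), 4),
    up = c(rnorm(6, 0, 1e-3), rnorm(6, 2, 1e-3))
  )
  toy$same <- toy$same + rnorm(12, 0, 1e-6)  # avoid exact rank collapse
  sp2 <- rank_features(decorrelate(zscore_features(toy), max_components = 2))
  tf2 <- top_features(toy, sp2, n_top = 2)
  expect_equal(tf2$relative_difference[tf2$feature == "up"], 100,
               tolerance = 0.01)
  expect_lt(abs(tf2$relative_difference[tf2$feature == "same"]), 1)

  expect_warning(top_features(tab, sp, n_top = 500), "truncated")
})

test_that("planted features occupy the top ranks across seeds", {
  hits <- vapply(1:15, function(i) {
    tab <- effect_cohort(seed = 900 + i, n = 16, f = 50, d = 3,
                         n_effect = 5)
    sp <- rank_features(decorrelate(zscore_features(tab)))
    all(top_features(tab, sp, n_top = 5)$feature %in% sprintf("f%03d", 1:5))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("domain analysis localizes a planted gait effect", {
  doms <- rep(c("gait", "speed", "imaging", "body"), each = 15)
  spec <- cohort_spec(14, 14, 60, effect_features = 1:15, effect_size = 2.5,
                      seed = 34)
  tab <- generate_feature_table(spec, feature_domains = doms)
  cfg <- quick_cfg(seed = 34, mc = 300L)
  grid <- domain_discrimination(tab, cfg = cfg)
  expect_setequal(grid$domain,
                  c("all features", "gait", "speed", "imaging", "body"))
  gait_idx <- grid$index[grid$domain == "gait"]
  others <- grid$index[!grid$domain %in% c("gait", "all features")]
  expect_true(all(gait_idx > others))
  expect_true(grid$significant[grid$domain == "gait"])

  # single-domain table reduces to the plain pipeline
  one <- generate_feature_table(spec, feature_domains = rep("gait", 60))
  g1 <- domain_discrimination(one, cfg = cfg)
  plain <- discriminate(tab, cfg)
  expect_equal(g1$index[g1$domain == "gait"], plain$index)
  expect_equal(g1$p_value[g1$domain == "gait"], plain$p_value)

  few <- generate_feature_table(spec,
                                feature_domains = c("solo",
                                                    rep("gait", 59)))
  expect_warning(domain_discrimination(few, cfg = cfg), "fewer than 2")
})

test_that("discriminate returns a coherent result object", {
  tab <- effect_cohort(seed = 35, n = 12, f = 40, d = 2, n_effect = 8)
  cfg <- quick_cfg(seed = 35, mc = 300L)
  res <- discriminate(tab, cfg)
  expect_s3_class(res, "discrimination_result")
  expect_equal(res$index, 100 * (1 - res$overlap))
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_identical(nrow(res$correct_distribution), cfg$n_repetitions)
  g <- glance(res)
  expect_identical(names(g)[1:3], c("index", "overlap", "p_value"))
  expect_identical(tidy(res), res$top_features)
})
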