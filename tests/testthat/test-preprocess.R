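test_that("z-scoring pools groups and drops constant features", {
  tab <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    group = rep(c("WT", "MUT"), each = 3),
    f1 = c(8, 10, 12, 8, 10, 12),
    f2 = rep(5, 6),
    f3 = c(1, 2, 3, 4, 5, 6)
  )
  expect_warning(z <- zscore_features(tab), "zero-variance")
  expect_identical(attr(z, "dropped_features"), "f2")
  expect_false("f2" %in% names(z))
  # pooled mean 0, SD 1
  expect_equal(mean(z$f1), 0)
  expect_equal(sd(z$f1), 1)
  # a value equal to the pooled mean maps to 0
  expect_equal(z$f1[2], 0)
  # definition check: a value two pooled SDs above the pooled mean -> z = 2
  x <- c(6, 8, 10, 12, 14)
  zx <- zscore_features(tibble::tibble(
    subject_id = sprintf("s%d", 1:5),
    group = c("WT", "WT", "WT", "MUT", "MUT"), f = x))
  expect_equal(zx$f[5], (14 - mean(x)) / sd(x))
})

test_that("z-scored ranking is invariant to affine rescaling of raw inputs", {
  tab <- effect_cohort(seed = 21, n = 10, f = 15, d = 1.5, n_effect = 5)
  scaled <- tab
  fc <- setdiff(names(tab), c("subject_id", "group"))
  for (i in seq_along(fc)) {
    scaled[[fc[i]]] <- 3.7 * tab[[fc[i]]] + i
  }
  r1 <- rank_features(decorrelate(zscore_features(tab)))
  r2 <- rank_features(decorrelate(zscore_features(scaled)))
  expect_equal(r1$rank_weight, r2$rank_weight, tolerance = 1e-8)
  expect_identical(r1$ordering, r2$ordering)
})

test_that("decorrelation whitens and collapses rank deficiency", {
  tab <- null_cohort(seed = 22, n = 12, f = 30)
  sp <- decorrelate(zscore_features(tab))
  cc <- cor(sp$transformed)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_lte(ncol(sp$transformed), nrow(tab) - 2L)
  # unit variance per component
  expect_equal(unname(apply(sp$transformed, 2, var)),
               rep(1, ncol(sp$transformed)))

  # duplicating a feature must not add a dimension: rank oracle via svd
  dup <- tab
  dup$dup <- tab[[3]]
  z1 <- zscore_features(tab)
  z2 <- zscore_features(dup)
  rank_oracle <- function(z) {
    m <- scale(as.matrix(z[, -(1:2)]), scale = FALSE)
    sum(svd(m)$d > 1e-8 * max(svd(m)$d))
  }
  expect_identical(rank_oracle(z2), rank_oracle(z1))
  expect_identical(ncol(decorrelate(z2)$transformed),
                   ncol(decorrelate(z1)$transformed))

  expect_error(decorrelate(zscore_features(null_cohort(seed = 1, n = 1,
                                                       f = 5))),
               "insufficient subjects")
})

test_that("already-uncorrelated input maps to itself up to sign and scale", {
  tab <- null_cohort(seed = 23, n = 20, f = 6)
  # PCA scores are exactly uncorrelated with distinct variances
  pc <- prcomp(as.matrix(tab[, -(1:2)]))$x
  tab2 <- dplyr::bind_cols(tab[1:2], tibble::as_tibble(pc))
  sp <- decorrelate(tab2, max_components = 6)
  # each transformed column must be collinear with exactly one input column
  cc <- abs(cor(pc, sp$transformed))
  expect_true(all(abs(apply(cc, 2, max) - 1) < 1e-8))
  expect_true(all(colSums(cc > 0.999) == 1))
})

test_that("re-decorrelating whitened data leaves it whitened on the same span", {
  # after whitening all components have variance 1, so the principal axes
  # are no longer unique; idempotency holds as an action on the whitened
  # subspace (same span, still perfectly decorrelated), not column by
  # column
  tab <- null_cohort(seed = 24, n = 15, f = 10)
  sp1 <- decorrelate(zscore_features(tab))
  tab2 <- dplyr::bind_cols(tab[1:2], tibble::as_tibble(sp1$transformed))
  sp2 <- decorrelate(tab2)
  expect_identical(ncol(sp2$transformed), ncol(sp1$transformed))
  cc <- cor(sp2$transformed)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # same subject-space span: cross-projection preserves all variance
  fit <- lm(sp1$transformed ~ sp2$transformed)
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
})

test_that("ranking maps standardized differences monotonically to 0-100", {
  sp <- toy_space(c(0, 1, 3))
  # make the zero-difference component exactly flat between groups
  sp$transformed[, 1] <- rep(seq_len(16), 2)
  r <- rank_features(sp)
  expect_equal(r$rank_weight[1], 0)
  expect_identical(r$ordering[1:2], c(3L, 2L))
  expect_equal(max(r$rank_weight), 100)
  expect_identical(which.max(r$rank_weight), 3L)
  expect_true(all(r$rank_weight >= 0 & r$rank_weight <= 100))
})

test_that("ranking order does not depend on subject order", {
  tab <- effect_cohort(seed = 25, n = 12, f = 20, d = 2, n_effect = 4)
  perm <- withr::with_seed(1, sample(nrow(tab)))
  r1 <- rank_features(decorrelate(zscore_features(tab)))
  r2 <- rank_features(decorrelate(zscore_features(tab[perm, ])))
  expect_equal(sort(r1$rank_weight), sort(r2$rank_weight),
               tolerance = 1e-6)
})

test_that("projection reports mean/SEM/SD ellipses with SEM = SD/sqrt(n)", {
  sp <- rank_features(toy_space(c(2, 1, 0.2), n_per_group = 16))
  pr <- project_2d(sp)
  expect_identical(pr$components, c("drf1", "drf2"))
  ell <- pr$ellipses
  expect_equal(ell$sem_radius, ell$sd_radius / sqrt(ell$n))
  for (gl in levels(pr$coords$group)) {
    for (ax in c("drf1", "drf2")) {
      row <- ell[ell$group == gl & ell$axis == ax, ]
      expect_equal(row$center, mean(pr$coords[[ax]][pr$coords$group == gl]))
      expect_equal(row$sd_radius, sd(pr$coords[[ax]][pr$coords$group == gl]))
    }
  }

  sp1 <- toy_space(c(1))
  expect_error(project_2d(rank_features(sp1)), "at least two")
})

test_that("identical groups produce coincident ellipse centers", {
  tab <- null_cohort(seed = 26, n = 40, f = 10)
  pr <- project_2d(rank_features(decorrelate(zscore_features(tab))))
  centers <- tidyr::pivot_wider(pr$ellipses[c("group", "axis", "center")],
                                names_from = "axis",
                                values_from = "center")
  gap <- sqrt(diff(centers$drf1)^2 + diff(centers$drf2)^2)
  # null separation is pure sampling noise plus selection of the top plane
  expect_lt(gap, 1.5)
})

test_that("a planted separation lands on drf1 at the oracle's whitened size", {
  # Pooled z-scoring rescales a planted shift d by the pooled SD of the
  # effect feature (which contains the shift itself), and label-blind
  # whitening can spread it over near-degenerate principal axes. The
  # independent oracle below redoes z-score -> whiten -> per-component
  # standardized difference with base R and predicts the drf1 group gap.
  d <- 4
  tab <- generate_feature_table(
    cohort_spec(100, 100, 20, effect_features = 1L, effect_size = d,
                seed = 27))
  g <- tab$group
  m <- scale(as.matrix(tab[, -(1:2)]))        # pooled z-scores
  pc <- prcomp(m)
  white <- sweep(pc$x, 2, pc$sdev, "/")       # unit-variance components
  d_comp <- apply(white, 2, function(x) {
    sp <- sqrt((var(x[g == "WT"]) + var(x[g == "MUT"])) / 2)
    abs(mean(x[g == "MUT"]) - mean(x[g == "WT"])) / sp
  })
  gaps <- abs(colMeans(white[g == "MUT", ]) - colMeans(white[g == "WT", ]))
  oracle_gap <- gaps[which.max(d_comp)]

  pr <- project_2d(rank_features(decorrelate(zscore_features(tab))))
  centers <- tidyr::pivot_wider(pr$ellipses[c("group", "axis", "center")],
                                names_from = "axis",
                                values_from = "center")
  gap <- abs(diff(centers$drf1))
  expect_equal(gap, unname(oracle_gap), tolerance = 1e-6)
  # the planted effect stays clearly visible despite the rescaling
  expect_gt(gap, 0.8)
  # and never exceeds the fully aligned bound d / pooled SD of the feature
  expect_lt(gap, d / sd(tab[[3]]) + 0.1)
})
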