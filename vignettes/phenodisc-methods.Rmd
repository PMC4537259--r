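---
title: "Methods: overlap-based discrimination and penetrance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap-based discrimination and penetrance statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodisc)
```

## The problem

High-throughput behavioral phenotyping platforms summarize each mouse by a
large vector of features — often more than a thousand channels covering
locomotion, posture, gait geometry, paw imaging and event sequences. With
cohorts of 10–20 animals per genotype, the analysis question is not "which
feature differs" but "how separable are the two groups as wholes, and how
likely is that separation to arise by chance?" phenodisc implements a
complete pipeline for that question, together with a per-subject
penetrance statistic and the covariate-adjusted gait regressions that
guard against speed and body-weight confounds.

## The discrimination model

Write $x_{f,i}$ for feature $f$ of subject $i$, with groups WT and MUT of
sizes $N$ and $M$.

1. **Pooled z-scoring.** Every feature is standardized with the mean and
   SD taken over all $N + M$ subjects together:
   $z_{f,i} = (x_{f,i} - \bar x_f) / s_f$. Pooling both groups keeps the
   transform label-blind; zero-variance features are dropped with a
   warning. The platform's internal normalization is not public, and
   pooled z-scoring is the same standardization the penetrance statistic
   defines, so one normalization serves both analyses.

2. **Decorrelation (whitening).** Many behavioral features are highly
   correlated (e.g. rearing counts and supported rearing counts). We form
   statistically independent linear combinations by principal-axis
   whitening of the pooled covariance: with SVD $Z = UDV^\top$ of the
   centered z-score matrix, the decorrelated features are
   $T = \sqrt{n-1}\,U_K$, which have exactly unit variance and zero
   mutual correlation. $K$ is capped at $\min(\text{rank}, n - 2)$ so
   downstream group covariances remain estimable — with $F \gg n$ the
   dimension reduction is forced, not optional. Estimation is label-blind
   so no group information leaks into the transform. Note that whitened
   output has a degenerate principal basis (all variances are 1);
   re-decorrelating whitened data therefore preserves the subspace and
   perfect decorrelation but not individual columns.

3. **Ranking.** Each decorrelated feature is scored by the absolute
   two-sample standardized mean difference (Cohen's $d$ with pooled SD)
   and scores are mapped linearly to 0–100% with the best feature at 100;
   ties break toward the lower index. The platform's proprietary ranking
   score is not disclosed; $|d|$ is the canonical effect-size screen and
   is fully testable. Ranking weighs every feature rather than selecting
   a subset, so information in weakly informative features is down-
   weighted, not discarded.

4. **The drf plane and Gaussian clouds.** The two top-ranked decorrelated
   features (drf1, drf2) form the visualization plane. Each group is
   approximated there by a Gaussian "cloud" (sample mean and covariance).
   Because $n$ per group is small, the covariance is shrunk toward its
   diagonal with intensity $\lambda = \min(1, \max(0, (K+1)/n - 0.05))$
   and ridge-floored so the smallest eigenvalue is at least $10^{-8}$.
   The plot shows, per group, the mean, the standard-error ellipse and
   the standard-deviation ellipse per axis (SEM $=$ SD$/\sqrt{n}$).

5. **Overlap and index.** Separability is the overlapping coefficient
   $\mathrm{OVL} = \int \min(p_A, p_B)$, and the **discrimination index**
   is $1 - \mathrm{OVL}$: 0 for identical clouds (chance level, 100%
   overlap), 100% for error-free discrimination. Identical clouds return
   exactly 1; in one dimension with equal variances the closed form
   $2\Phi(-|\mu_A - \mu_B| / 2\sigma)$ is used and other 1D cases are
   integrated numerically; in higher dimensions OVL is estimated by
   Monte-Carlo importance sampling over the equal-weight mixture,
   $\widehat{\mathrm{OVL}} = \frac1m \sum \min(p_A, p_B)/p_{\text{mix}}$.
   At the default $10^5$ draws the estimator agrees with the 1D closed
   form within 0.01 (tested for $d \in \{0, 0.5, 1, 2, 3\}$).

6. **Chance estimation.** The full pipeline (z-score, whiten, rank, fit,
   index) is repeated on random 80% subsamples of each group, with
   correct labels and with randomly permuted labels. Re-ranking happens
   *inside* every repetition: selecting the top plane on the full data
   first would leave the selection optimism out of the null and inflate
   significance. The chance p-value is the overlap of the two index
   distributions, computed as $\sum_b \min(\hat p^{\text{corr}}_b,
   \hat p^{\text{null}}_b)$ on a shared histogram with Freedman–Diaconis
   bin widths. With small groups the randomized-label distribution is
   *not* centered at zero — finite-sample optimism from re-ranking —
   and its mean shrinks as cohorts grow; treating the null as zero would
   overstate significance.

7. **Top features.** To interpret a separation we score each original
   feature by $\sum_k |{\rm cor}(x_f, t_k)| \cdot w_k/100$ (loading on
   highly ranked components), rescale to 0–100%, and report the relative
   normalized difference $100\,(\bar x_{MUT} - \bar x_{WT}) /
   (|\bar x_{WT}| + |\bar x_{MUT}| + \varepsilon)$. These are presented
   as a signature, deliberately without per-feature significance tests:
   with hundreds of features combed for differences, feature-wise
   $p < .05$ would be misleading.

Domains (gait, speed, paw position, …) can be analyzed separately with
`domain_discrimination()`, which runs the identical pipeline per feature
subset plus all features combined.

## Penetrance z-scores

The per-subject statistic is the mean absolute z-score across features,
$z_i = \frac1F \sum_f |z_{f,i}|$, with z-scores pooled over both groups.
Under a null Gaussian cohort $E[z_i] = \sqrt{2/\pi} \approx 0.798$. The
variability of $z_i$ across subjects separates two readings of a
phenotype:

- **trait** — a subject's deviations are correlated across features; at
  perfect correlation ${\rm SD}(z_i)$ equals the per-feature SD of
  $|z|$, $\sqrt{1 - 2/\pi} \approx 0.603$;
- **state** — deviations are independent per feature; ${\rm SD}(z_i)$
  shrinks at the $1/\sqrt F$ rate.

If a mutation is incompletely penetrant — some mutants extreme in every
test, others indistinguishable from controls — both the group mean
$z_{MT}$ and its variability $\sigma_{MT}$ exceed the control values.
Group means are compared with a label-permutation test on $z_i$ and
variabilities with a Brown–Forsythe-type permutation test on
$|z_i - \text{group median}|$ (10,000 permutations by default).
Permutation tests were chosen because group sizes are small and $|z|$ is
skewed; no named test is standard for this statistic. At $n = 16$ per
group the variability test has limited power, so simulation studies of
incomplete penetrance read the direction event
$\sigma_{MT} > \sigma_{WT}$ (rate ≈ 0.82 under the calibration settings
below) rather than test significance. Subjects missing more than half
their features are excluded with a warning; otherwise $z_i$ averages the
available features.

## Gait allometry

Stride and stance durations shorten nonlinearly with locomotor speed, and
paw image area grows linearly with body weight. Genotype comparisons of
gait features therefore go through covariate adjustment:

- `power_fit()` fits $y = a x^b$ by OLS on $\log y \sim \log x$
  (exactly linear-Gaussian when the noise is multiplicative log-normal);
- `linear_fit()` fits $y = c + \beta x$;
- `compare_regressions()` performs the standard interaction/elevation
  decomposition on the fitting scale: slope equality (interaction term),
  elevation equality at common slope, and the combined 2-df F test
  against a single shared line. Because such comparisons are easily
  driven by extreme animals, a leave-one-out range of each group's slope
  is reported as an influence diagnostic.

## The synthetic cohort generator

No raw per-mouse feature matrices from the original platforms are public,
so the package ships a generator reproducing the statistical structure
the analysis assumes, making every stage testable end to end:

- control features are zero-mean, unit-variance Gaussian with
  block-equicorrelation (`block_sizes`, `within_block_rho`) — the
  simplest structure capturing "many features are correlated" and
  analytically tractable for oracles;
- a per-subject latent trait $u_i$ enters every feature with loading
  $\sqrt{\rho_t}$ (features rescaled to keep unit variance), so the
  between-feature correlation of a subject's deviations equals
  `trait_rho` exactly — the knob behind the trait/state contrast;
- a standardized shift `effect_size` is added on `effect_features` for a
  fixed-size random subset of `round(penetrance_fraction * M)` mutants;
- gait tables obey $\text{stride} = a\,\text{speed}^b e^\varepsilon$
  with log-normal noise (keeping durations positive and the log-log fit
  exact) and paw area linear in weight; speeds are log-normal around
  15 cm/s, weights normal around 25 g.

Everything is driven by one explicit seed; identical specifications give
bit-identical tables, and no global RNG state is touched.

What the generator does *not* emulate: real features are often counts,
latencies or proportions with skewed marginals; feature blocks have
heterogeneous, non-equicorrelated structure; and real effect patterns are
not a uniform shift on a subset. Passing tests demonstrate that the
pipeline's statistical machinery is correct and calibrated under the
stated model — not that any particular published discrimination value is
reproduced. The original studies' headline indexes depend on proprietary
raw data and are out of scope by design.

## Numerical choices and degenerate inputs

- Whitening tolerance: singular values below
  $\max(\dim) \cdot \epsilon_{\text{machine}} \cdot d_1$ are treated as
  rank deficiency (duplicated features collapse, tested).
- Overlap Monte-Carlo uses log-densities throughout; clouds a million
  SDs apart underflow to index 100% without instability.
- Covariance shrinkage guarantees positive-definite 2D clouds even at
  $n = 3$ per group.
- The histogram overlap p-value falls back to Sturges bins when the IQR
  is zero, and to $p = 1$ when both distributions are a single point.
- Permutation p-values use the add-one estimator
  $(1 + \#\{|T_b| \ge |T|\})/(1 + B)$, which is valid (never zero).
- Subsampling requires at least 3 subjects per group after the 80% draw;
  smaller designs error with advice rather than degrade silently.

## Simulation sizes used by the test suite

Calibration and power checks run at the cohort sizes typical of these
studies: $16 + 16$ mice, 100–200 features. The chance p-value calibration
uses 200 null cohorts at 100 repetitions per label condition and 500
Monte-Carlo overlap points; signal detection uses 100 cohorts with
$d = 3$ on 20 of 200 features; penetrance moment checks use 400-subject
cohorts where Monte-Carlo error is a few thousandths; the gait type-I
study uses 500 seeds. Repetition and Monte-Carlo counts are configurable
(`resample_config()`) and all reported numbers scale in accuracy with
them.

## Known limitations

- The decorrelation and ranking are principled stand-ins for a
  proprietary algorithm; published indexes from the original platforms
  are not expected to be numerically reproduced.
- The index is defined through cloud overlap on the top-2 plane;
  separations living in higher whitened dimensions are only partially
  captured there (as in the original visualization).
- With all features standardized to equal variance, whitening axes are
  near-degenerate on null data; the per-repetition ranking handles the
  resulting selection noise, but single-run drf planes on null data are
  arbitrary up to rotation.
- Permutation tests with $n \le 10$ per group have coarse p-value
  granularity; the defaults assume $n \ge 12$ or so.
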