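# phenodisc

Overlap-based two-group discrimination, penetrance z-scores and
speed/weight-adjusted gait regressions for high-dimensional behavioral
phenotyping of mouse models.

Automated phenotyping platforms describe each animal by hundreds to
thousands of behavioral features, with typical cohorts of only 10–20
mice per genotype. phenodisc answers the question such studies ask:
*how separable are mutant and control cohorts as wholes, and how likely
is that separation by chance?* It is aimed at behavioral
neuroscientists and biostatisticians analyzing subjects-by-features
tables from any phenotyping pipeline.

## The method in brief

For a feature table with groups WT and MUT:

1. **z-score** every feature over the pooled cohort:
   z<sub>f,i</sub> = (x<sub>f,i</sub> − x̄<sub>f</sub>)/s<sub>f</sub>;
2. **decorrelate** by principal-axis whitening of the pooled covariance
   (statistically independent combinations of the original features,
   K ≤ n − 2 components);
3. **rank** each decorrelated feature by |Cohen's d| between groups,
   scaled to 0–100%;
4. fit a per-group **Gaussian cloud** (diagonal-shrunk covariance) on
   the top-2 plane (drf1, drf2) and compute the overlapping coefficient
   OVL = ∫ min(p_A, p_B);
5. report the **discrimination index = 1 − OVL** (0 = chance,
   100% = error-free discrimination) and estimate its **chance
   p-value** as the overlap between index distributions obtained from
   repeated subsampling with correct versus randomized labels.

The package also implements the **penetrance statistic**
z<sub>i</sub> = (1/F) Σ<sub>f</sub> |z<sub>f,i</sub>| with permutation
tests on the group means and variabilities of z<sub>i</sub> (elevated
σ<sub>MT</sub> flags incomplete penetrance), power-law
(stride ∼ speed<sup>b</sup>) and linear (paw area ∼ weight) gait
regressions with an interaction/elevation comparison of the group
lines, and a fully seeded synthetic cohort generator (correlated
feature blocks, latent trait correlation, incomplete penetrance) so the
entire pipeline is testable without proprietary raw data.

## Worked example

```r
library(phenodisc)

spec <- cohort_spec(n_control = 16, n_mutant = 16, n_features = 200,
                    block_sizes = rep(10, 20), within_block_rho = 0.3,
                    effect_features = 1:20, effect_size = 2.5,
                    trait_rho = 0.1, seed = 42)
tab <- generate_feature_table(spec)

res <- discriminate(tab, resample_config(n_repetitions = 200,
                                         n_overlap_samples = 5000,
                                         seed = 42))
res
#> <discrimination_result> index 97.1% (overlap 0.029), p = 0
#>   200 repetitions per label condition
glance(res)
#> # A tibble: 1 × 6
#>   index overlap p_value median_correct median_null n_repetitions
#>   <dbl>   <dbl>   <dbl>          <dbl>       <dbl>         <int>
#> 1  97.1  0.0292       0          0.965       0.540           200
```

A planted standardized shift of 2.5 on 20 of 200 features yields a
97.1% discrimination index: the two fitted clouds overlap by only
0.029. The correct-label index distribution (median 0.965) clears the
randomized-label null (median 0.540 — note the null is well above zero
at n = 16, the finite-sample optimism of re-ranking inside each
repetition), so the histogram overlap p-value is 0. The top features
recover the planted channels with their relative normalized difference:

```r
tidy(res)
#> # A tibble: 10 × 5
#>   feature rank_weight relative_difference mean_WT mean_MUT
#>   <chr>         <dbl>               <dbl>   <dbl>    <dbl>
#> 1 f015          100                 100.0  -0.188     2.79
#> 2 f013           98.0               100.0  -0.283     2.37
#> 3 f018           97.6               100.0  -0.276     2.65
#> ...
```

`autoplot(res$projection)` draws the drf-plane scatter with mean, SEM
and SD ellipses per group; `autoplot(res)` the two index distributions.

Penetrance and gait stages:

```r
penetrance_analysis(tab, seed = 42)
#> <penetrance_result> 32 subjects, 200 features
#>   z_WT = 0.793 (sigma 0.058), z_MT = 0.806 (sigma 0.064)
#>   mean test p = 0.5566, variability test p = 0.4736 (two.sided)

gt <- generate_gait_table(16, exponent_b = -0.4, group_speed_shift = 4,
                          seed = 42)
power_fit(dplyr::filter(gt, group == "WT"))
#> <power_fit WT> y = 0.4532 * x^-0.3711  (R2 = 0.762, n = 16)
compare_regressions(gt)
#> <line_comparison> (loglog scale)
#>   slope difference    -0.04312  (p = 0.5822)
#>   elevation difference +0.02279  (p = 0.2346, common slope)
#>   combined F = 0.874 (p = 0.4283)
```

Here the groups differ in speed but share one stride–speed law, and the
line comparison correctly finds no genotype effect after speed
adjustment (mean z_i ≈ 0.80 matches the null expectation √(2/π); the
cohort's group shift lives in the feature means, not in extremeness
heterogeneity, so both penetrance tests are null).

An end-to-end run over several models — simulation or CSV input,
discrimination, per-domain grids, penetrance and gait — is driven by a
JSON config through `run_report()`; see
`inst/extdata/demo_config.json`. A thin CLI with subcommands
`simulate`, `discriminate`, `penetrance`, `gait` and `report` is in
`inst/cli/phenodisc.R`.

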