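# qherit — quantile-specific narrow-sense heritability from family data

`qherit` asks whether the heritability of a quantitative phenotype depends
on where the phenotype lies in its population distribution. For a
right-skewed trait such as fasting triglycerides, a single heritability
number presumes that offspring-on-parent regression lines are parallel
across the whole trait distribution; `qherit` estimates the narrow-sense
heritability h² as a *function* of the trait quantile and tests that
parallel-lines assumption. It is aimed at quantitative geneticists and
epidemiologists working with two-generation family cohorts (pedigree +
longitudinal exams), and ships a Gaussian-copula pedigree simulator so the
whole pipeline is testable without access-restricted cohort data.

## The method

1. **Adjustment.** Phenotypes are age- and sex-adjusted per cohort by OLS
   on `female, age, age², female×age, female×age²` (optionally after a log
   transform); adjusted value = residual + cohort mean, averaged over each
   individual's exams.
2. **Pairs.** Weighted offspring-parent (weights ½/½ with both parents, 1
   with one), offspring-midparent, full-sib (all kᵢ(kᵢ−1) ordered pairs,
   weight 1/(kᵢ−1)) and spouse pair sets are built from the pedigree, with
   familial degrees of freedom Σkᵢ−2 (offspring-parent) and Σ(kᵢ−1)
   (full-sib).
3. **Quantile slope process.** At each τ on a grid (default 5th–95th
   percentile, 91 levels) the weighted check loss
   Σᵢ wᵢ ρ_τ(yᵢ − a − b xᵢ), ρ_τ(u) = u(τ − 1[u<0]),
   is minimised exactly by a vertex-pivoting simplex solver (interior-point
   fallback), and the covariance of the 91 slopes is estimated by a pair-
   or family-level bootstrap.
4. **Heritability.** Slopes convert via the Falconer relations
   h² = 2β_OP/(1+r_spouse), h² = β_OM, and
   h² = [√(1+8·r_spouse·β_FS) − 1]/(2·r_spouse),
   with delta-method standard errors.
5. **Tests.** Orthogonal-polynomial contrasts (linear/quadratic/cubic)
   across the grid, the change in slope per one percentile, and the
   90th−10th percentile slope difference, all referred to t distributions
   on the familial degrees of freedom using the bootstrap covariance.

## A worked example

```r
library(qherit)

cohort <- generate_cohort(signature_config(n_families = 1000, seed = 42))
cohort <- apply_eligibility(cohort)           # age >= 16, no lipid meds
adj    <- adjust_phenotypes(cohort)           # per-cohort age/sex adjustment
rs     <- weighted_correlation(build_spouse_pairs(adj, cohort))
op     <- build_op_pairs(adj, cohort)
fit    <- qherit(op, r_spouse = rs, n_boot = 200, seed = 42,
                 resample_unit = "family")
summary(fit)
```

```
Quantile-specific heritability fit (OP pairs, n = 4632, df = 2314)
  spouse correlation: 0.154
  traditional slope: 0.3328 +/- 0.0209 (r = 0.31) -> h2 = 0.577 +/- 0.036
  slope change per 1 percentile: 0.005688 +/- 0.0006997 (P = 6.92e-16)
  quadratic P = 0.0186, cubic P = 0.172
  beta(0.90) - beta(0.10) = 0.4377 +/- 0.0547 (P = 1.94e-15)

Heritability at selected quantiles:
  tau  slope slope_se    h2 h2_se
 0.10 0.1341   0.0139 0.232 0.024
 0.25 0.1989   0.0203 0.345 0.035
 0.50 0.3029   0.0328 0.525 0.057
 0.75 0.4454   0.0381 0.772 0.066
 0.90 0.5717   0.0576 0.991 0.100
```

Read this as: a single "traditional" heritability of 0.58 hides a fourfold
spread — offspring in the lowest decile of the simulated triglyceride-like
distribution show h² ≈ 0.23 while those in the top decile show h² ≈ 0.99,
and the linear rise of about 0.0057 in slope units per percentile is
highly significant. These data come from the package's lognormal-margin
generator, whose constant latent familial correlation produces exactly
this raw-scale signature (`plot(fit)` draws the h² curve with its 95%
bootstrap band). On real file-based data, replace the simulated cohort
with `read_cohort("pedigree.tsv", "exams.tsv")` — a miniature synthetic
example of the format lives in `inst/extdata/` — or drive everything from
one configuration with `run_pipeline(run_config(...))`, which writes
`slopes.csv`, `h2_curve.csv`, `table1.csv`, `trend_tests.json` and
`run_summary.json`.

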