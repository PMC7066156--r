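---
title: "Quantile-specific heritability: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-specific heritability: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qherit)
```

## The question

Classical quantitative genetics summarises familial resemblance for a trait
in a single number: the narrow-sense heritability $h^2$, the fraction of
phenotypic variance attributable to additive genetic effects. For a
right-skewed metabolic trait such as fasting triglycerides, a single $h^2$
presumes that the regression of an offspring's phenotype on a parent's is
the same whether the offspring sits at the 10th or the 90th percentile of
the trait distribution — graphically, that the conditional quantile curves
of offspring on parent form parallel lines.

*Quantile-dependent expressivity* is the alternative: the strength of the
genetic effect depends on where the phenotype lies in its distribution.
`qherit` estimates $h^2$ as a *function* of the trait quantile and tests
the parallel-lines null.

## From family data to heritability curves

### Adjustment

Phenotypes are age- and sex-adjusted separately per cohort by ordinary
least squares on an intercept plus five covariates — `female`, `age`,
`age^2`, `female x age`, `female x age^2` — pooling each cohort's exam
records, optionally after a natural-log transform. The adjusted value is
the residual *plus the cohort grand mean*, which keeps the phenotype in
concentration units so that regression slopes remain interpretable; each
individual's adjusted exams are then averaged into one value. Pooling all
exam waves into one model per cohort (the age terms absorb aging across
waves) is the default; `scope = "cohort_exam"` fits one model per wave
instead, since the reference analyses do not state which was used.

### Pairs and weights

Four weighted pair sets are built from the pedigree:

* **offspring–parent (OP)** — weight 1/2 each for the offspring–father and
  offspring–mother pair when both parents are measured, weight 1 when only
  one is; degrees of freedom $\sum_i k_i - 2$ with $k_i$ offspring per
  family;
* **offspring–midparent** — the offspring against the mean of both
  parental values (families with both parents only), weight 1;
* **full-sib (FS)** — all $k_i(k_i-1)$ ordered sib pairs per sibship,
  each weighted $1/(k_i-1)$; degrees of freedom $\sum_i (k_i - 1)$;
* **spouse** — one pair per parental couple, giving the spouse correlation
  $r_{spouse}$ used in the conversions below.

The FS weighting deserves a note: "equal weight to each sibling" is
ambiguous between weight 1 per ordered pair and a weight that equalises
each sibling's total contribution. We default to $1/(k_i-1)$ per pair so
that every sibling contributes total weight 1 as the dependent member —
large sibships then cannot dominate the fit — and provide
`flat_weights = TRUE` for the literal per-pair reading. Sibships are keyed
on both parent ids, so half-sibs are excluded.

### The quantile slope process

At each level $\tau$ of the grid (default $0.05, 0.06, \dots, 0.95$; 91
levels) we minimise the weighted check loss

$$\hat\beta(\tau) = \arg\min_{a,b} \sum_i w_i\, \rho_\tau(y_i - a - b x_i),
\qquad \rho_\tau(u) = u(\tau - \mathbf{1}[u<0]).$$

Each level is fitted independently; "simultaneous" estimation in the
classical software this mirrors refers to joint *inference* across levels,
which here comes from the bootstrap: resampling pairs (or whole families)
with replacement, refitting the full process per replicate, and taking the
empirical covariance of the 91 slopes. The point fits use the original
sample; the covariance feeds every cross-level test.

The minimisation is an exact linear program. Because the design has one
covariate plus an intercept, every optimum lies on a line through two data
points, and the solver walks vertex to vertex: starting from the weighted
least-squares slope and the weighted $\tau$-quantile intercept, it
repeatedly rotates the line about one of its two basis points to the
optimal slope along that edge — a weighted-quantile selection over the
pairwise slopes $s_i = (y_i - y_c)/(x_i - x_c)$ with weights
$w_i |x_i - x_c|$ — until neither basis point admits an improving rotation.
Each rotation minimises a convex piecewise-linear function exactly, so the
walk is monotone and finite. A Frisch–Newton interior-point solver (with a
Mehrotra predictor–corrector, complementarity gap below $10^{-10}$ of the
response scale) acts as fallback on exact-tie plateaus; tests check both
against exhaustive enumeration of all two-point lines, which for this
design is an exact independent LP solve.

Ties among candidate slopes are resolved by the first grid crossing of the
cumulative weight (a canonical vertex); degenerate predictors (all $x$
equal) are an error, and degenerate bootstrap replicates are redrawn (more
than 10% redraws aborts) so the replicate count stays fixed.

### Falconer conversions and tests

Slopes become heritabilities through the standard relations, with
$r = r_{spouse}$ entering because phenotypic assortative mating inflates
familial resemblance:

$$h^2_{OP} = \frac{2\beta_{OP}}{1+r}, \qquad
h^2_{OM} = \beta_{OM}, \qquad
h^2_{FS} = \frac{\sqrt{1 + 8 r \beta_{FS}} - 1}{2r}
\;\;\xrightarrow{\,r\to 0\,}\;\; 2\beta_{FS}.$$

Standard errors follow by the delta method with $r$ treated as a fixed
constant (the reference results report, e.g., $2 \times 0.0074 / 1.15
\approx 0.013$ for the OP standard error, which this convention
reproduces; published FS standard errors deviate slightly from the delta
method and we keep the delta method with this note). The FS conversion is
continuous at $r = 0$ via the series limit, used below $|r| < 10^{-8}$.

Constancy of $\beta(\tau)$ is tested with orthogonal polynomial contrasts
of degree 1–3, built by QR orthonormalisation of the Vandermonde basis on
the *actual* grid so non-default grids work: the statistic is
$t = c'\hat\beta / \sqrt{c' V c}$ with $V$ the bootstrap covariance,
referred to a $t$ distribution on the pair set's familial degrees of
freedom, two-sided. The linear contrast is also returned rescaled so that
$c'\hat\beta$ is the least-squares change in slope per one percentile. A
difference test compares $\hat\beta(0.90) - \hat\beta(0.10)$ using the two
bootstrap variances and their covariance.

## The synthetic cohort generator

Real two-generation cohort data of the kind that motivated this package
are access-restricted, so the generator is a first-class module: every
pipeline property is demonstrated on data whose truth is known.

Per family it draws a latent multivariate normal vector (father, mother,
$k$ children) with constant correlations — `rho_spouse` between parents,
`rho_po` parent–child, `rho_ss` child–child — and maps each latent value
through $\Phi$ and the inverse margin CDF (a Gaussian copula). Covariate
effects (`sex_effect`, `age_effect`, `age2_effect`) and per-exam noise are
added on the measurement scale; positive-support margins are floored at
0.01, an assay detection floor that also keeps the log transform defined.

The key property: with a *normal* margin the conditional quantiles of
child given parent are parallel lines (constant slope process — the null);
with a *lognormal* margin the same constant latent correlation produces
raw-scale slopes that rise with $\tau$, attenuating under a log transform.
Quantile-dependent expressivity is thus induced purely by the nonlinear
margin transformation; the generator does not claim this is the biological
mechanism of any real trait, only that it reproduces the observable
signature.

Defaults are chosen once to resemble the motivating cohort study:
sibship-size mix `(1:0.25, 2:0.38, 3:0.22, 4:0.09, 5:0.04, 6:0.02)`
(roughly the published sibship table plus a share of singletons),
`rho_spouse = 0.15` (the published raw-scale spouse correlation),
`rho_po = rho_ss = 0.35`, lognormal margin with `meanlog = 0.6`,
`sdlog = 0.6` (median ≈ 1.8 mmol/L, right-skewed like triglycerides),
female shift −0.3 mmol/L, mild age effects, two exams per subject with
noise SD 0.2 mmol/L, offspring ages uniform on 20–60 with parents offset
+25 years. `null_config()` swaps in a normal margin (mean 2.4, SD 1.2,
matching the published cohort mean); `signature_config()` is the lognormal
preset.

What the generator does **not** emulate: shared-environment correlation
distinct from additive genetics (spouse/parent/sib correlations are set
freely rather than derived from a variance-component model), missing
parents, secular trends across exam waves, medication use, or
non-Gaussian dependence. Passing tests therefore demonstrate correctness
of the estimator under a known copula model, not unbiasedness for any
real cohort.

### The Monte-Carlo oracle

`oracle_quantile_slope()` provides ground truth for recovery tests by a
route independent of the production solver: it simulates pairs directly
from the latent model (including the exam-averaged noise and detection
floor, but no pedigree assembly and no covariates, since the pipeline
removes those by adjustment) and minimises the empirical expected check
loss by golden-section search over the slope, profiling the intercept out
as a $\tau$-quantile. The profile objective is convex in the slope, so the
search is reliable.

## Numerical and design choices

* **Bootstrap resampling unit.** The pair bootstrap mirrors the classical
  software's default; pairs within a family share members and are
  dependent, so the package also offers (and its own calibration runs use)
  the family-level cluster bootstrap. The run summary records the choice.
* **Medication exclusion** is applied at the exam-record level (a
  subject's medicated exams are dropped, unmedicated ones kept), the less
  destructive reading of a subject-level criterion stated without
  per-exam detail; `medication_rule = "subject"` gives the strict reading.
  Individuals left without exams are dropped from analysis but retained as
  pedigree link rows when their children remain.
* **Log transform** uses the natural log; slope-ratio comparisons are
  invariant to the base.
* **Problem sizes in the test-suite.** The type-I calibration runs 500
  cohorts of 300 families with 100 bootstrap replicates each — about
  4.6 million quantile fits, which the vertex solver completes in a few
  minutes; power and recovery checks use 50 replicates of 3000 families at
  three grid levels, and the solver-equivalence checks run exhaustive
  enumeration on instances of up to 200 points. These sizes are scaled-down
  study analogues chosen to make the suite's Monte-Carlo bands tight enough
  to be meaningful.
* **Determinism.** Every stochastic entry point takes one integer seed,
  restores the caller's RNG state, and derives all internal streams from
  that seed; identical seeds give byte-identical outputs.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(synthetic = signature_config(n_families = 1000, seed = 42),
                  pair_kinds = c("OP", "FS"), n_boot = 200, seed = 42,
                  resample_unit = "family", out_dir = "results")
res <- run_pipeline(cfg)
res$fits$OP          # print method: slopes, h2, trends
plot(res$fits$OP)    # h2 curve with 95% band
res$table1           # one row per pair kind
```

## Limitations

The Falconer conversions assume additive genetics with at most phenotypic
assortative mating; shared environment is not separated from additive
variance, so $h^2$ here is an upper bound in the usual sense. Per-level
quantile fits may cross (no monotonicity correction is applied, matching
the reference procedure). Bootstrap covariances with few replicates are
noisy; the trend tests treat them as known, which is slightly
anticonservative for small `n_boot`.
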