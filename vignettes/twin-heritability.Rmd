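---
title: "Estimating the heritability of microbiome taxa from twin designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the heritability of microbiome taxa from twin designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinbiome)
```

## The question and the design

Vaginal microbiome composition differs reproducibly between individuals
and between ancestry groups, but how much of that variation is
attributable to host genetics is hard to establish from unrelated
subjects. The classical twin design answers it by comparison:
monozygotic (MZ) co-twins share all their segregating genes, dizygotic
(DZ) co-twins on average half, while both kinds of pairs share rearing
environment. If a taxon's abundance is more strongly correlated within
MZ than within DZ pairs, the excess resemblance points to additive
genetic variance.

`twinbiome` implements this biometrical approach end to end for
species-level taxa abundance tables: sample screening, proportion
transformation, taxa filtering, ACE-family variance-component models fit
by full maximum likelihood, likelihood-ratio model comparison,
profile-likelihood intervals, cohort descriptive statistics, and a
synthetic cohort generator used to calibrate the whole chain.

## The model

For a pair with transformed phenotypes $(y_1, y_2)$ the ACE model
assumes a bivariate normal with a single grand mean $\mu$ and covariance

$$
\Sigma_{\mathrm{MZ}} =
\begin{pmatrix} a^2+c^2+e^2 & a^2+c^2 \\ a^2+c^2 & a^2+c^2+e^2 \end{pmatrix},
\qquad
\Sigma_{\mathrm{DZ}} =
\begin{pmatrix} a^2+c^2+e^2 & \tfrac12 a^2+c^2 \\ \tfrac12 a^2+c^2 & a^2+c^2+e^2 \end{pmatrix},
$$

where $a^2$ is additive-genetic variance, $c^2$ common-environment
variance and $e^2$ unique-environment variance (which absorbs
measurement error, hence $e^2 > 0$). The log-likelihood is the sum of
bivariate normal log-densities over pairs; it depends on the data only
through per-zygosity sufficient statistics, which makes repeated
evaluation essentially free and model fitting fast even for very large
simulated cohorts. Narrow-sense heritability is the standardized
additive component $h^2 = a^2 / (a^2 + c^2 + e^2)$.

Submodels AE, CE and E fix the omitted components at zero. Dropping a
component and registering the decline in fit gives the likelihood-ratio
chi-square test (df = difference in free parameters) and the change in
AIC; `heritability_test()` fits the whole ladder and reports $h^2$ from
the AE model with the AE-versus-E p-value, because shared-environment
variance is rarely separable from additive-genetic variance at typical
twin-cohort sizes.

### Parameterization

The default `direct` parameterization leaves $a^2$ and $c^2$ unbounded
(only $e^2$ is kept positive, through an internal log transform). This
is deliberate: near-zero true components then yield point estimates and
confidence bounds that can go negative, which is informative about
sampling noise rather than an error, and it keeps the null hypothesis
$a^2 = 0$ in the interior of the parameter space so the
likelihood-ratio statistic has its standard central chi-square(1)
reference distribution. The alternative `path` parameterization squares
path coefficients, constraining $a^2, c^2 \ge 0$; under it the null
lies on the boundary and the unadjusted LRT is conservative (no
boundary-mixture correction is applied — a documented caveat, not a
default).

### Optimization and numerical choices

Fitting uses five deterministic starts — a method-of-moments start
($\hat a^2 = 2(\widehat{\mathrm{cov}}_{MZ} - \widehat{\mathrm{cov}}_{DZ})$,
etc.) plus four fixed dispersed perturbations — each refined by
Nelder–Mead and polished by BFGS; the best optimum is kept. Non-positive
definite covariance points return a `-Inf` sentinel rather than an
error, which the optimizers handle gracefully. On datasets small enough
for exhaustive search, the estimates agree with a coarse-then-refined
grid-search oracle to within grid resolution (this is one of the test
suite's calibration checks).

Confidence intervals are profile-likelihood by default: a component is
fixed on a walk away from the MLE, the other parameters re-optimized,
and the bound located where the profile deviance crosses the
chi-square(1) quantile (3.8415 at 95%). A cheaper Wald interval from the
numerical Hessian is available (`confint(fit, method = "wald")`),
clearly labelled, and only roughly agrees in small samples.

## The transformation and the filters

Taxa proportions are variance-stabilized with $y = \arcsin\sqrt{p}$
(radians, range $[0, \pi/2]$), the conventional transform for
proportions entering linear Gaussian models; values within $10^{-9}$ of
the boundary are clamped, anything further out is an error.

Two screens precede modelling:

* **Read depth.** Samples need at least 5000 reads (`min_reads`,
  inclusive). The default denominator for proportions is the per-sample
  total read count including unassigned reads, which is robust to
  truncated taxon lists; screening and renormalizing on assigned reads
  are both available since conventions differ between upstream
  pipelines.
* **Prevalence/abundance.** A taxon is analyzable when it reaches a
  within-subject proportion of at least 10% in at least 20% of subjects
  (both inclusive; the expanded exploratory screen is 1% in 2.5% of
  subjects). We read the two conditions jointly — the abundance
  threshold must be met *in* the qualifying subjects — because the
  disjoint reading admits taxa that are near-absent in most carriers
  and provide almost no covariance information; the disjoint rule
  remains available as `mode = "disjoint"`. Filtering is applied to the
  analysis population (after singleton exclusion), pooled across strata
  by default.

Only complete pairs enter the model: a lone twin carries no information
about within-pair covariance, so singletons are counted and excluded
before any modelling statistic is computed. The same logic cascades
through the optional age sensitivity subset (`age_cutoff`, retaining
participants of age at most the cutoff, e.g. 51 years as a menopause
screen): if the filter removes one member, the pair is dropped.

## Descriptive statistics

`summarize_cohort()` reproduces the conventional cohort
characteristics table: per-stratum min / median (IQR) / mean (sd) / max
with missingness for continuous variables, counts for categorical ones,
a Yates-continuity-corrected chi-square for 2×2 contrasts and a Welch
(unequal-variance) t-test computed from group summaries for continuous
contrasts. The Yates correction and the Welch form are the defaults
because they are what published cohort tables of this size typically
report; the uncorrected chi-square is available with
`correct = FALSE`. For the bacterial-vaginosis contrast, "not sure"
responses and missing values are excluded from the test; other
categorical tests exclude missing values only.

## The synthetic cohort generator

`generate_cohort()` draws the data structure the analysis assumes so the
whole chain can be exercised and calibrated without access-controlled
human data: latent $y = \mu + A + C + E$ with the MZ/DZ genetic
correlation structure, focal-taxon proportion $\sin^2(y)$ after
clamping $y$ to $[0, \pi/2]$, sparse nuisance taxa sharing part of the
remaining read mass, overdispersed negative-binomial depths (so some
samples genuinely fail the 5000-read screen), a 5% singleton rate, and
two ancestry strata. Counts are exact multinomial draws via sequential
conditional binomials, vectorized across samples. Everything is
reproducible from the spec's single seed.

**Calibration of the variance scale.** Clamping censors the Gaussian
tails, and at a total latent variance near the squared range
(e.g. $a^2 + e^2 = 1$ on a range of $\pi/2$) the censoring is heavy
(20–40% of draws) and attenuates the standardized genetic component by
about 0.06 — enough to corrupt parameter-recovery studies. The
generator therefore keeps the default total latent variance at 0.04
(sd 0.2), at which clamping affects under 1% of draws (asserted in the
test suite) and the latent ACE decomposition survives the
back-transform essentially intact. Standardized components are
scale-free, so heritability truths such as $h^2 = 0.347$ are unaffected
by this choice; simulation scenarios state component *ratios* at this
calibrated scale.

**What the generator does not emulate.** Real vaginal taxa are
zero-inflated and often bimodal (absent, or community-dominant);
community state types, pH coupling and longitudinal dynamics are not
modelled. Passing calibration tests therefore demonstrates that the
estimator and pipeline are correct and well-calibrated *under the
model's own assumptions*, not that real abundance data satisfy those
assumptions.

## Calibration results the package checks for itself

The test suite and the acceptance script recompute, from scratch:

* recovery of generating heritability (0.4 and 0.347) to within ±0.03
  at 2000+2000 pairs;
* type-I error of the AE-vs-E LRT within [0.03, 0.07] over 500 null
  replicates of 300+300 pairs;
* empirical coverage of the 95% profile interval within [0.92, 0.98]
  over 300 replicates at 500+500 pairs;
* agreement of the Falconer moment estimate $2(r_{MZ} - r_{DZ})$ with
  the ML heritability. The two estimators target the same quantity but
  the moment estimator is much noisier, so their per-dataset difference
  is mean-zero sampling noise with sd ≈ 0.02 even at 10000+10000 pairs;
  agreement is therefore assessed on the average difference over ten
  replicate cohorts of that size;
* the cohort characteristic machinery against published-style printed
  inputs (Yates chi-squares 5.21 / 9.48 / 6.66, Welch |t| = 4.45, and
  the standardization arithmetic 0.1428/(0.1428+0.2683) = 0.3473).

Problem sizes were chosen to make each check statistically decisive at
a few minutes of compute on a single core; they are stated alongside
each result.

## A worked example

```{r example}
spec <- cohort_spec(n_mz = 500, n_dz = 500, seed = 42)
cohort <- generate_cohort(spec)
cohort

dir <- tempfile()
paths <- write_cohort(cohort, dir)
res <- run_pipeline(paths["taxa"], paths["metadata"],
                    analysis_config(ci = TRUE), file.path(dir, "out"))
subset(res$table2, taxon == "Lactobacillus_crispatus")
```

The `table2.tsv` report gives one row per component (A, E) per taxon
per stratum with unstandardized and standardized estimates and profile
intervals; `nested_models.tsv` holds the full ACE/AE/CE/E ladder with
the likelihood-ratio drop tests; `run.log` records every filter's
input/output accounting. Reports contain no timestamps, so identical
inputs and configuration reproduce them byte-for-byte.

## Known limitations

* No ADE model, sex-limitation, bivariate models or GxE moderation.
* No FIML for half-missing pairs — complete pairs only, by design.
* The LRT under the `path` parameterization is conservative at the
  boundary (no 50:50 mixture correction).
* Per-test alpha of 5%; a Bonferroni-adjusted column is emitted in the
  reports for transparency but is not the headline decision rule.
* Profile bounds can fail to bracket in pathological fits; the affected
  side is reported as `NA` with a warning rather than guessed.
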