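---
title: "Normal-anchored trimodal mixture screening: model, tests, and design choices"
author: "trimodr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-anchored trimodal mixture screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimodr)
```

## The problem

A gene can behave as an oncogene in one patient subgroup and as a tumor
suppressor in another. The observable signature is *tri-modal association*:
tumors whose expression of the gene is unusually **low** and tumors whose
expression is unusually **high** both do worse — shorter survival, higher
tumor grade — than tumors whose expression is **similar to normal tissue**.
trimodr detects this signature in two stages: a per-gene constrained
mixture fit that decides whether low/middle/high modes exist at all, and a
battery of one-tailed association tests applied to the resulting patient
groups.

## The mixture model

For one gene, let $\vec{x}_{tumor}$ be its expression in tumor samples and
$\vec{x}_{normal}$ its expression in normal samples, both on a log scale.
The model is a three-component Gaussian mixture with three constraints that
encode the biology:

* **ordered means** $\mu_1 \le \mu_2 \le \mu_3$, so the components are
  interpretable as low / middle / high;
* **one shared standard deviation** $\sigma$, which stops a wide component
  from swallowing samples that plainly sit in another mode;
* **normal anchoring**: every normal sample is forced to come from
  component 2, so "middle" means "similar to normal" by construction rather
  than by post-hoc labeling.

The joint log likelihood is

$$
LL = \sum_{i=1}^{\#tumor} \log\!\Big(\sum_{j=1}^{3} \pi_j\, f(x_{tumor,i};
\mu_j, \sigma)\Big) \;+\; \sum_{i=1}^{\#normal} \log f(x_{normal,i}; \mu_2,
\sigma),
$$

with $f$ the Gaussian density and $\vec\pi$ the mixing proportions.

### EM updates and the ordering constraint

The E-step computes responsibilities $\gamma_{ij}$ for tumor samples only
(normal samples have no latent membership — they are anchored). The M-step
updates $\pi_j$ as responsibility column means, and each $\mu_j$ as the
responsibility-weighted tumor mean, with all normal values entering the
numerator and denominator of $\mu_2$. When the unconstrained means violate
the ordering, the offending adjacent means are *pooled*: $\mu_1 = \mu_2$
(or $\mu_2 = \mu_3$, or all three) is set to the common weighted average of
the merged components' samples. This is the exact constrained maximizer for
an adjacent-violation, and merged fits are exactly the non-trimodal
verdicts. One guard goes beyond the three adjacent-violation cases: if
pooling components 1–2 leaves the pooled mean above $\mu_3$ (possible only
for pathological responsibilities), all three means are pooled; this keeps
the update well defined and never produces NaN. Finally $\sigma$ pools the
weighted tumor residuals with the normal residuals around $\mu_2$.

### Responsibility weighting: two modes

Standard mixture EM weights the E-step densities by the current mixing
proportions ($\gamma_{ij} \propto \pi_j f_j$). A defensible alternative
drops the $\pi_j$ weighting and uses plain density ratios
($\gamma_{ij} \propto f_j$), which biases the fit toward equal effective
weights. `fit_trimodal_em(weighting = ...)` implements both:

* `standard` (default): genuine EM on the stated likelihood; the
  log-likelihood trace is provably non-decreasing, which the test suite
  asserts on random fixtures. The downstream formulas — the $\pi$ update as
  posterior column means, the $\pi$-weighted cutoff crossing — presuppose
  this posterior, which is why it is the default.
* `paper_literal`: the plain density-ratio variant. It carries no ascent
  guarantee, but in practice converges and recovers well-separated modes
  equally well (the suite checks recovery under both modes).

### Initialization, convergence, numerical floors

The model has no closed-form fit and EM is deterministic given a start, so
these choices matter and are fixed defaults:

* $\mu^0$ = 10th/50th/90th percentiles of the pooled tumor+normal values;
  $\pi^0 = (0.15, 0.70, 0.15)$; $\sigma^0$ = pooled standard deviation.
  One deterministic start by default; `restarts = k` adds $k$ seeded random
  quantile-triple starts and keeps the best log likelihood.
* Convergence: absolute log-likelihood change below `tol = 1e-6`, capped at
  `max_iter = 500`.
* `sigma` is floored at $10^{-3} \times$ the pooled data range, preventing
  a component from collapsing onto a point mass.
* All density arithmetic is done in log space; a sample for which all three
  densities underflow is hard-assigned to the nearest mean.

### Trimodality, cutoffs, mode assignment

A converged fit is **trimodal** when both mean gaps are strictly positive
(tolerance $10^{-8}$) and every $\pi_j > 0.01$. For trimodal fits the two
mode boundaries are the points where adjacent $\pi$-weighted densities
cross; with a shared $\sigma$ the log density ratio is linear in $x$, so the
crossing has the closed form

$$
cutoff_{12} = \frac{\mu_1^2 - \mu_2^2 - 2\sigma^2 \log(\pi_1/\pi_2)}
{2(\mu_1 - \mu_2)},
$$

and analogously for $cutoff_{23}$. For very unequal proportions the
crossing can leave the interval $[\mu_1, \mu_2]$; the cutoff then falls
back to the 10% (or 90%) empirical quantile of the tumor values
(linear-interpolation type-7 quantile) and is flagged. Tumor samples are
hard-assigned by comparing their value to the two cutoffs; values exactly
on a cutoff go to the middle mode, the conservative direction
("similar to normal"). The observed label proportions are the *empirical*
$\pi$, which downstream filters use in place of the model $\pi$ because
they describe the actual patient groups being tested.

## Association tests

**Survival.** The low and high modes are each contrasted against the middle
mode in a Cox proportional-hazards model on the mode factor (middle as
reference), with all follow-up administratively censored at 20 years.
`p12` is the one-sided p value for "low has *higher* hazard than middle",
computed as the upper tail of the low coefficient's Wald statistic
($p = 1 - \Phi(z)$); `p23` is the analogue for high. The one-sided
orientation is the point of the screen: protective effects are not
evidence.

**Grade.** `grade_trend_test` restricts to one contrast mode plus the
middle mode, tabulates membership across grades 1–3 with integer scores,
computes the Cochran–Armitage trend chi-square, and signs its square root
by the direction of the trend: the one-tailed p value is small exactly when
higher grades are enriched for the contrast mode, is 0.5 for a flat table,
and exceeds 0.5 when the trend points the other way. The suite checks this
against an independently coded textbook Cochran–Armitage formula.

**Adjustment.** `multivariable_survival` fits the same Cox model with a
declared covariate set (continuous expression covariates, categorical
subtype with Basal as the reference level, age, stage, lymph nodes, ...).
Mode contrasts keep one-sided p values; covariates are reported two-sided,
since no direction is hypothesized for them. Listwise deletion handles
missing covariates; collinear terms are dropped with a warning.

**Cross-cohort overlap.** `overlap_hypergeometric` scores the overlap of
two gene lists within a shared universe by the upper-tail hypergeometric
probability.

## The screen

`screen_cohort` runs per gene: fit → trimodality verdict → empirical mode
proportions all at least `min_mode_prop` (default 5%) → the four one-tailed
tests. A gene is a *candidate* when all four p values fall below `alpha`
(default 0.05). `cross_cohort_candidates` intersects cohorts under a
`strict` policy (all four tests significant everywhere) or a `relaxed` one
(significant in the named discovery cohorts, and at least trend-correct —
all four p < 0.5 — elsewhere).

Cohorts without normal samples cannot anchor the middle component. For
them, modes are imposed by expression rank via `split_by_proportions`,
using proportions learned elsewhere (e.g. averaged from cohorts that do
have normals). Supplied proportions are renormalized to sum to one, since
published averaged proportions may not. Stratum sizes are
$\lfloor n p_1 \rfloor$ low and $\lfloor n p_3 \rfloor$ high, with every
rounding leftover assigned to the middle stratum — again the conservative
direction — and rank ties broken by stable input order.

No multiple-testing correction is applied across genes; the screen reports
raw per-gene p values and leaves genome-wide error control to the user, who
should treat candidate lists as hypotheses for replication, not
discoveries.

## The synthetic-data generator

`simulate_screen_cohort` produces cohorts with exactly the structure the
model assumes, so every stage is testable without patient data:

* **Expression**: planted genes draw tumor values per mode from
  $N(\mu_j, \sigma^2)$ with defaults $\mu = (-4, 0, 3)$, $\sigma = 1$, and
  100/250/150 tumor plus 50 normal samples — a configuration in which the
  three modes are visibly separated at realistic cohort size; null genes
  are unimodal $N(\mu_2, \sigma^2)$ with no clinical linkage.
* **Survival**: exponential event times with hazard
  `baseline_hazard` × HR(mode), defaults 0.1/year and hazard ratios 3 for
  both outer modes — a strong but plausible prognostic effect. Censoring is
  an independent exponential calibrated to censor 20% of middle-mode
  samples, plus the same 20-year administrative cap the tests use. The Cox
  model is semiparametric, so the exponential baseline is a transparency
  choice, not an assumption the tests inherit.
* **Grade**: a three-level proportional-odds model, baseline grade
  probabilities (0.20, 0.45, 0.35) for middle-mode samples and a
  `grade_trend = 1.5` log-odds shift toward higher grades in the outer
  modes — the simplest mechanism that yields the monotone trend the test
  targets.
* Each gene has its own random sub-stream derived from (seed, gene index),
  so per-gene data are reproducible and independent of gene order.

What the generator does **not** emulate: probe-level noise, batch and
platform effects, correlated genes, non-Gaussian expression tails,
informative censoring, or copy-number co-amplification. Passing tests on
this generator show the algorithmic machinery is correct under its own
assumptions; they do not show the modeling assumptions hold in any real
cohort.

## Behavior on unimodal (null) genes — a known limitation

A three-component mixture is over-specified for unimodal data, and
maximum-likelihood fitting *prefers* using spare components to model
distribution tails. Consequently a large fraction of pure-noise genes —
roughly half at the default sample sizes, measured in this package's test
suite — receive a formally trimodal verdict (strictly ordered means, all
$\pi_j > 0.01$), often with small outer components; converged null fits
that do merge their means are genuinely non-trimodal, but merging is not
the typical outcome. The trimodality flag alone is therefore a weak
filter, and the screen never relies on it alone: the 5% minimum
mode-proportion filter and the requirement that *four* independent
one-tailed association tests all reach significance are what keep the
false-candidate rate low. In the planted-signal experiments in the test
suite, 200 null genes alongside one planted risk gene yield the planted
gene as the sole candidate in at least 90% of runs.

## Problem sizes used in the test suite

The suite fits the reference simulation (500 tumor + 50 normal values) 50
times for parameter-recovery checks, runs 100 random fixtures for the
ascent property, 200 null replicates for test calibration, and 20
full screens of 201 genes for planted-signal recovery — sizes chosen so the
whole suite completes in minutes while keeping every check at the cohort
scale the method targets.

## Known limitations

* The number of components is fixed at three; genes with two or four
  genuine expression states are forced into the nearest three-mode
  description.
* The shared-variance assumption is load-bearing: heteroskedastic modes
  shift the cutoff locations.
* One-sided Wald p values rely on large-sample normality of the Cox
  coefficient; with very few events or tiny modes they are approximate,
  and the functions flag degenerate fits rather than guessing.
* The trimodality verdict on unimodal data is permissive (see above);
  interpret it only together with the proportion filter and association
  tests.
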