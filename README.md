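# trimodr

Screening tumor expression for genes whose **low and high expression both
mark worse outcome** — the signature of a gene that can act as an oncogene
in one patient subgroup and a tumor suppressor in another.

## The model

For each gene, tumor expression (log scale) is modeled as a three-component
Gaussian mixture with ordered means and one shared standard deviation,
anchored to matched normal samples: every normal sample is forced into the
middle component, so the middle mode means "similar to normal" by
construction. The joint log likelihood is

    LL = Σ_tumor log( Σ_j π_j f(x; μ_j, σ) ) + Σ_normal log f(x; μ_2, σ),

with μ₁ ≤ μ₂ ≤ μ₃. The constrained EM pools adjacent means whenever the
unconstrained update violates the ordering. A converged fit is *trimodal*
when both mean gaps are strict and every π_j > 0.01; the low/middle/high
boundaries are the expression values where adjacent π-weighted densities
cross,

    cutoff₁₂ = (μ₁² − μ₂² − 2σ² log(π₁/π₂)) / (2(μ₁ − μ₂)),

falling back to the 10%/90% tumor quantiles when the crossing leaves
(μ₁, μ₂) (analogously for cutoff₂₃).

Downstream, each outer mode is contrasted against the middle mode with
one-tailed tests: Cox proportional-hazards Wald contrasts for survival
(censored at 20 years; p12 = low worse than middle, p23 = high worse), and
signed Cochran–Armitage trend tests for tumor grade 1–3. A screen candidate
must be trimodal, have every mode at ≥ 5% of patients, and pass all four
tests at p < 0.05; candidates can be replicated across cohorts with
hypergeometric overlap statistics. Cohorts without normal samples are
split by expression rank into externally supplied mode proportions.

## Worked example

```r
library(trimodr)

# one gene with planted low/middle/high structure:
# tumor = 100 N(-4,1) + 250 N(0,1) + 150 N(3,1), normal = 50 N(0,1)
sim <- simulate_mixture_gene(sim_config(), seed = 42)
fit <- fit_trimodal_em(sim$x_tumor, sim$x_normal, gene_id = "GENE_A")
fit
#> Trimodal mixture fit for GENE_A
#>   mu    = (-3.9810, -0.0064, 2.9975)
#>   pi    = (0.1965, 0.5130, 0.2905)
#>   sigma = 1.0118
#>   loglik = -1216.4171 after 30 iterations (converged)
#>   trimodal: TRUE
#>   cutoffs: c12 = -2.2408, c23 = 1.6894
#>   empirical pi = (0.196, 0.516, 0.288)
```

The fit recovers the generating means (−4, 0, 3), shared σ = 1 and
low-mode weight 0.20; the cutoffs are the density crossings used for hard
assignment. Testing the assigned modes against mode-linked synthetic
clinical data:

```r
clin <- simulate_clinical(sim$labels_true, sim_config(), seed = 43)
st <- trimodal_survival_test(fit$labels, clin$time_years, clin$event)
c(p12 = st$p12, p23 = st$p23)
#>          p12          p23
#> 3.164656e-16 1.487308e-16
grade_trend_test(fit$labels, clin$grade, "low")$p
#> [1] 7.200049e-11
```

Both outer modes show significantly worse survival (one-tailed p12 and
p23) and a significant trend toward higher grade — the tri-modal
association signature. `screen_cohort()` runs this per gene over a whole
matrix and flags candidates; see the vignette
(`vignettes/trimodal-screening.Rmd`) for the model details and design
choices.

A command-line interface covers the same pipeline
(`inst/cli/trimodr simulate | fit | test | screen`), writing TSV/JSON-lines
outputs plus a run manifest with seeds and parameters.

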