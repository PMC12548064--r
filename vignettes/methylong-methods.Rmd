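---
title: "Methods: longitudinal candidate-CpG methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal candidate-CpG methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylong)
```

## Scope and data model

`methylong` analyses candidate-region DNA methylation in a two-timepoint
cohort contrasting ART-conceived with naturally conceived children. The
unit of observation is a blood sample (child × timepoint): cord blood at
birth, peripheral blood at a later age (3–22 years in the design the
package emulates). Methylation arrives as a probes × samples matrix in
beta (methylated fraction, in (0,1)) or M scale; all modelling happens on
M-values, M = log2(β/(1−β)), where array measurement error is closer to
homoscedastic. The bundled manifest covers the 25 CpGs of the
*BRCA1*/*NBR2* bidirectional promoter (hg19 17:41,277,059–41,278,712),
but every entry point accepts an arbitrary manifest of the same shape.

The package assumes upstream array processing (background correction,
normalization, probe QC, cell-type deconvolution) has already happened:
its inputs are post-QC values, optionally accompanied by estimated cell
fractions as extra covariates. Those steps need raw intensity data and
reference panels and are deliberately out of scope.

## Preprocessing

**Twin deduplication.** Twins violate the independence assumption of the
per-sample models. `dedup_twins()` keeps one child per `twin_pair_id`
uniformly at random (seeded), dropping both timepoint rows of the other
twin. Deduplication is a separate, explicit step rather than part of the
generator so that a sheet can also be analysed as delivered.

**Outlier filter.** Per probe and per timepoint dataset, samples outside
median ± k·MAD are excluded (`mad_filter()`, default k = 5). Two
deliberate choices:

* the MAD is *unscaled* — the literal median of absolute deviations from
  the median, without the 1.4826 normal-consistency constant. The scaled
  variant is one argument away (`constant = 1.4826`); with it, the same
  multiplier excludes less.
* the filter is a *single pass*: median and MAD are computed once on the
  input, and no re-iteration follows. Retained values therefore all lie in
  the frozen interval by construction, which the tests assert against a
  brute-force evaluation of the rule.

A zero MAD (more than half the values identical) makes the rule vacuous;
the filter then excludes nothing and warns rather than erroring, since
such probes can still carry usable variation in the tails.

**Covariate encoding.** Fixed effects are encoded with the reference
levels: conception natural, smoking "No", BMI "Normal", sex female.
Parity enters as a continuous integer (0–4) and maternal age as continuous
years; BMI categories and smoking as indicator sets. Rows missing any
required covariate are flagged and excluded per model (complete-case); no
imputation is attempted.

## Cross-sectional association

Per probe and timepoint, `fit_cpg_lmm()` fits the random-intercept model

$$ M_{ij} = X_i\beta + b_{plate(i)} + \varepsilon_{ij}, \qquad
   b \sim N(0, \sigma^2_{plate}),\ \varepsilon \sim N(0, \sigma^2) $$

by REML (`lme4::lmer`; an ML switch is exposed). The 96-well plate is the
only random effect: it captures the dominant technical batch structure of
methylation arrays. Inference on the ART coefficient uses the two-sided
Wald test against the **normal** reference (z, CI multiplier 1.96), not a
t with estimated degrees of freedom — with cohorts in the hundreds the
difference is negligible, and the choice is stated rather than hidden.
Raw p-values are BH-adjusted within each timepoint's probe family
separately (25 probes in the default manifest).

Numerical edge cases: a plate variance estimated at the boundary (zero) or
a failed mixed fit triggers a documented fallback to ordinary least
squares, which *is* the generalized-least-squares solution at zero plate
variance; the result is flagged `converged = TRUE` with
`plate_variance = 0`. Only when the OLS fallback also fails (e.g. a rank
deficient design leaves the ART column inestimable) is `converged = FALSE`
returned with a missing p-value; such probes are never silently dropped.
The tests pin the fallback to the OLS coefficient to 1e-6 and the interior
case to a closed-form GLS oracle at the fitted variance components to
1e-8.

## Within-child change

The change analysis asks whether the ART–methylation association differs
between birth and the later age. Because the two timepoints are measured
in different tissues, raw M-value differences conflate tissue shift with
true change; instead each timepoint is residualized on its technical and
child-level drivers (sex; child age for the postnatal data; plate random
intercept), and the residuals are standardized *within* the timepoint
dataset (sample SD, n−1 denominator). The per-child statistic

$$ d_c = z^{postnatal}_c - z^{birth}_c $$

is regressed on ART with maternal covariates (age, smoking, BMI, parity)
by OLS, with Wald inference and BH correction as above.

Design choices worth flagging:

* **Sign convention.** d = postnatal − birth, so a *negative* ART
  coefficient means an ART-associated elevation present at birth fades
  with age. The direction is an argument (`direction`) and is carried into
  the report, because "difference between birth and later age" is
  genuinely ambiguous.
* **Standardization invariance.** Any positive affine rescaling of one
  timepoint's M-values leaves the standardized residuals, and hence all
  change results, unchanged; a test asserts this to 1e-8. This is the
  property that makes cross-tissue differencing defensible.
* **Complete pairs.** Children missing either timepoint — including
  through an outlier exclusion at exactly one timepoint — contribute
  nothing to d for that probe. With duplicate samples per child and
  timepoint the sheet is rejected outright.
* **Degenerate probes.** If the technical model explains a probe exactly
  (residual SD 0) standardization is undefined and the probe errors out;
  if all d are identical the ART coefficient is reported as 0 with p = 1
  and a warning rather than an error, since a constant change vector is a
  legitimate (if extreme) null outcome.

## Power simulation

`simulate_power()` implements a Monte-Carlo power analysis for the
two-group comparison
$$ M_i = \mu + \delta X_i + \sigma T_i, \qquad T_i \sim t_\nu, $$
with defaults μ = 1.2, δ = 0.13, σ = 0.49, ν = 10 — an effect size and
noise scale taken from a large discovery EWAS of ART, with mild heavy
tails. σ multiplies the t variate, so the total noise SD is
σ·√(ν/(ν−2)) ≈ 0.548; under this reading the closed-form normal
approximation Φ(|δ|/SE − z_{1−α/2}) gives 80.1% power at 1,112 / 365
subjects and α = 0.05/25 = 0.002, which is what the Monte-Carlo run
reproduces (the alternative reading, σ as the total SD, does not). Each
iteration applies the two-sided Wald test to the group coefficient of the
OLS fit — for a two-group design, the group-mean difference over its
pooled-variance standard error. The exact test behind the published
power figure is not documented anywhere we could verify; the OLS Wald
choice is recorded here as an assumption, validated by reproducing the
published 80%-at-4.5× result.

`required_multiplier()` searches the smallest k on a 0.1-step grid such
that power at (⌈k·n₁⌉, ⌈k·n₂⌉) reaches the target. Every evaluation reuses
one seed (common random numbers), making the estimated power curve
monotone enough in n for bisection after an exponential bracketing pass;
the bracketing avoids ever simulating at the cap unless the target is
genuinely unreachable. The simulation processes iterations in blocks
bounded at ~2×10⁷ values so memory stays flat regardless of n.

## The synthetic cohort generator

`generate_cohort()`/`generate_methylation()` define the study conditions
under which the pipeline is validated. The defaults reproduce the
motivating cohort's marginals: group sizes 250/105, 14 ART twin pairs
(generated as extra co-twins so deduplication is exercised for real),
two-timepoint availability 97.2%/76.2% with the observed birth-only vs
postnatal-only split among single-timepoint children, published
smoking/BMI/parity/sex/multiple-birth tables including BMI missingness
(5.6%/2.9%), maternal age truncated-normal on [17, 45] with means
31.3/33.8, and postnatal ages drawn from the observed age bands truncated
to the study's 3–22-year range. Values the source tables do not determine
were fixed once as plausible for this field and are exposed as arguments:
maternal-age SD 4.5 years (between-mother variation in national birth
cohorts), plate SD 0.1 M-units (a modest but visible batch effect),
samples randomized to ⌈n/96⌉ plates. Twin co-twins share all maternal
covariates but draw sex independently — a simplification (real twin pairs
are often same-sex by zygosity) that is irrelevant to the marginals the
tests consume.

Methylation is simulated directly on the M scale as intercept + per-probe
timepoint-specific ART effect + plate effect (drawn once per plate,
shared across probes) + σ·t(ν) noise. What this deliberately does *not*
emulate: probe-to-probe correlation along the promoter, beta-scale
heteroscedasticity, array type-I/type-II probe chemistry, cell-type
composition shifts between cord and peripheral blood, or age trends in
methylation. Passing tests therefore demonstrate that the *statistical
machinery* is correct under the stated model — unbiased recovery of
injected effects, nominal type-I error, correct filter and adjustment
algebra — not that the pipeline is robust to every artefact of real array
data.

`study_reference_cohort()` is different in kind: a deterministic,
blockwise-assigned sheet whose marginal counts equal the published cohort
table exactly. It exists to exercise descriptive reporting
(`describe_cohort()`) against known percentages; its joint covariate
distribution is artificial and unsuitable for model fitting.

## Problem sizes and determinism

The shipped test suite validates the stochastic properties at sizes chosen
to keep a full run in the low minutes on one core while leaving the
Monte-Carlo bands meaningful: 200 null CpG-datasets (8 cohorts × 25
probes) for the type-I checks with a 3-SE acceptance band around 0.05; 200
replicates at 1,112/365 for CI coverage of an injected δ = 0.13 (≥ 93%
observed); 1,000 random vectors against the brute-force MAD and BH
oracles; 10,000 iterations for the headline power figures. All generators
and searches are seeded; two pipeline runs with one seed produce
byte-identical outputs, and the run manifest records every derived seed.

## Known limitations

* Wald z inference ignores small-sample df; with < ~50 samples per fit the
  CIs will be anticoverage-prone. The cohort sizes this package targets are
  an order of magnitude above that.
* The change model inherits whatever confounding survives residualization;
  covariates affecting *both* timepoints' residual scale (e.g. batch ×
  group interactions) are not modelled.
* The power module covers the cross-sectional two-group comparison only,
  without covariates or mixed structure — matching the simple model behind
  the published sample-size statement, not the full analysis model.
* BH adjustment is applied within a 25-probe family; the procedure's FDR
  guarantee is marginal per family, not global across timepoints.
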