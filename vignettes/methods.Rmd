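---
title: "Methods: genome-wide sodium-interaction scans of blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide sodium-interaction scans of blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodiumGxE)
```

## The problem and the model

Blood pressure (BP) responds to dietary sodium, but the response varies
between people, and part of that variability is genetic. A genome-wide
gene–environment interaction scan looks for variants whose genotype
modifies the sodium–BP slope. For each variant, two nested Gaussian linear
models are fitted by least squares:

$$\text{model 1: } BP = \beta_0 + \beta_G G + \beta_E E + \gamma'Z$$
$$\text{model 2: } BP = \beta_0 + \beta_G G + \beta_E E +
  \beta_{GE}\,G \times E + \gamma'Z$$

where $E$ is daily sodium consumption in mEq/day, $G$ the coded genotype
and $Z$ the adjustment covariates (by default 20 principal components,
age, sex and BMI). The interaction is tested with the 1-df likelihood
ratio statistic under the Gaussian maximum-likelihood variance profile,

$$\Lambda = n \,\ln(RSS_1 / RSS_2) \;\sim\; \chi^2_1 \text{ under }
  H_0\!: \beta_{GE} = 0 .$$

This is the standard likelihood ratio for nested ordinary least squares
fits; the Wald statistic $(\hat\beta_{GE}/\widehat{SE})^2$ agrees with it
asymptotically, which the test suite checks on well-conditioned synthetic
data. A 2-df joint test of $\beta_G = \beta_{GE} = 0$ is available behind
the `joint` flag of `fit_interaction_lrt()`, but it is deliberately not
part of the default pipeline: the scan's question is whether the *slope*
differs by genotype, not whether the locus is associated with BP at all.

### Genotype codings

Four codings of a biallelic variant are supported (`code_genotype()`):
**dosage** (posterior-expected coded-allele count, in $[0,2]$),
**additive** (best-guess count, $\{0,1,2\}$), **dominant** (carrier of at
least one coded allele) and **recessive** (homozygote of the coded class;
a contrast such as "GG vs AG/AA" is recessive coding of G). Best-guess
genotypes are the posterior argmax; ties are broken toward the lower
genotype class — a deterministic, reference-conservative rule — and
flagged. Either allele can be designated as coded, because a recessive
effect of the major allele is a real possibility and is exactly how a
major-homozygote contrast arises.

### Genomic control and staged significance

Residual population structure inflates interaction statistics mildly. The
scan therefore estimates $\lambda = \text{median}(\Lambda_i)/0.4549364$
(the $\chi^2_1$ median) and divides every statistic by
$\max(\lambda, 1)$. The floor at 1 means the correction can only be
conservative — deflating below the null expectation would defeat the
purpose of guarding against false positives.

Candidate loci pass staged gates (`two_stage_evaluate()`): *suggestive*
if the GC-corrected discovery $P < 1\times10^{-5}$; *replicated* if
additionally the replication $P < 0.05$ with the same sign of
$\hat\beta_{GE}$; *genome-wide significant* if additionally the pooled,
study-site-adjusted $P < 5\times10^{-8}$. Two conventions here were
genuinely open and are package decisions: genomic control is applied to
the discovery stage only (the replication set is small and hypothesis
driven, so its statistics are not genome-wide distributed), and the
combined stage uses the raw P from the site-adjusted pooled fit.

## Phenotype preparation

- BP is the mean of the available (one or two) measurements. For subjects
  on antihypertensive medication the untreated BP is imputed by adding
  10 mm Hg (SBP) and 5 mm Hg (DBP); turning this off is the measured-BP
  sensitivity mode.
- Hypertension is SBP ≥ 140, DBP ≥ 90, or medication, with inclusive
  thresholds.
- Daily sodium excretion is estimated from a casual spot urine sample by a
  power-law estimator,
  $\widehat{Na}_{24h} = s\,\bigl(Na_{spot}/Cr_{spot}\cdot
  \widehat{Cr}_{24h}\bigr)^{k}$, with predicted 24-h creatinine a linear
  function of age, weight and height. All coefficients are configuration
  values (`sodium_formula()`); `tanaka_coefficients()` ships the published
  Tanaka defaults (spot Na in mEq/L, spot Cr in mg/dL, output mEq/day).
  Keeping the coefficients as configuration rather than constants matters
  because several such estimators (Kawasaki, INTERSALT) share the template
  and differ only in coefficients; the tests exercise the template through
  degenerate and round-trip coefficient sets, not through any particular
  published set.
- Unit conversions use 1 mEq = 1 mmol and a sodium molar mass of
  23.0 mg/mmol with half-up rounding at the presentation layer. The
  integer molar mass is the clinical convention, and it is the choice that
  reproduces the usual printed figures exactly (164.8 mEq/day → 3,790
  mg/day; 147.5 → 3,393; 2 g/day → 87 mmol/day); the physical 22.99 would
  round 147.5 mEq to 3,391 mg. The molar mass is an argument for anyone
  who wants the physical value.
- Subjects missing BMI, SBP, DBP or daily sodium are excluded; a subject
  missing several variables is excluded once but counted under every
  reason, so the exclusion log columns need not sum to the excluded count.

## Variant quality control

`compute_variant_qc()` evaluates call rate ≥ 0.95, exact-test HWE
$P \ge 1\times10^{-6}$, MAF ≥ 0.01 (dosage/additive), coded-genotype
frequency ≥ 0.01 (dominant/recessive) and imputation $R^2 \ge 0.8$.
Thresholds are read as printed ("fail if below"), so equality passes. MAF
and HWE use hard calls, because the exact test needs integer counts.

The Hardy–Weinberg exact test is computed from scratch: the conditional
distribution of the heterozygote count given the allele counts is built by
the standard two-step recurrence, carried in log space so tables with
thousands of samples cannot overflow, and the two-sided P-value sums all
outcomes whose conditional probability does not exceed the observed one
(the conventional definition, not the mid-P variant). The test suite
verifies it against an independent log-factorial enumeration oracle over
every genotype triple with $n \le 100$ and every allele configuration up
to $n = 200$.

## The power calculation

`estimate_power()` reproduces a Monte-Carlo power analysis of the 1-df
test. Each iteration draws $E \sim N(\mu_{Na}, \sigma_{Na}^2)$ with
$\mu_{Na} = 164.8$, $\sigma_{Na} = 37.9$ mEq/day, a genotype $G$
(Binomial(2, f) additive; Bernoulli(f) dominant/recessive, where f is the
effect *allele* or effect *genotype* frequency respectively), builds

$$BP = \beta_E E + \beta_{GE} G E + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_r^2),$$

fits the nested models, and records rejection at $\alpha = 10^{-5}$.
Defaults: $n = 4{,}527$, 1,000 iterations, $\beta_E = 0.041426$ (SBP) or
$0.019897$ (DBP) mm Hg per mEq/day, $\beta_{GE}$ a multiple
(0.5–2.0) of $\beta_E$. The analytic cross-check uses the non-central
$\chi^2_1$ approximation with
$NCP = n\,\beta_{GE}^2\,\mathrm{Var}(G)\,\sigma_{Na}^2/\sigma_r^2$.

### The residual-variance reconstruction

The generative model above describes *age-, sex-, BMI-adjusted* BP and
states no residual term, yet a deterministic model would give power 1, so
a residual SD must be supplied. The marginal SDs of SBP/DBP
(≈19.2/11.9 mm Hg in cohorts of this kind) are the wrong quantity — they
include the covariate signal that the adjustment removes. We therefore
reconstructed $\sigma_r$ by inverting the non-centrality relation at the
reference power values this calculation is known to produce: each of the
five available (trait, model, frequency, ratio) anchor points implies a
$\sigma_r$, and the implied values agree closely within trait
(17.09–17.35 mm Hg for SBP; 10.84–10.99 for DBP). The defaults are
therefore **17.2 mm Hg (SBP)** and **10.9 mm Hg (DBP)** — consistent with
an adjusted-BP interpretation, since removing an age/sex/BMI $R^2$ of
15–20% from a 19.2 mm Hg marginal SD lands exactly there. The parameter
stays exposed (`resid_sd`) because it is a reconstruction, not a printed
fact.

## The synthetic-cohort generator

`gen_cohort()` produces cohorts with the statistical structure the
analysis assumes, so that every downstream stage has a testable ground
truth:

- **Genotypes** are Binomial(2, MAF) under Hardy–Weinberg equilibrium,
  independent across variants.
- **Imputation noise**: with target dosage-vs-truth $R^2 < 1$, each
  subject's observed genotype class leaks to an adjacent class with
  probability $\lambda$ (side chosen at random for heterozygotes), and the
  genotype posterior spreads mass $\lambda$ symmetrically around the
  observed class; dosage is always the posterior expectation. A purely
  deterministic symmetric leak would leave dosage an affine function of
  the truth and $R^2$ pinned at 1, which is why the mechanism includes the
  stochastic class jump. $\lambda$ is calibrated per variant by bisection
  on the realised $R^2$, using common random numbers so the calibration
  target is monotone; the realised value is recorded in the variant
  metadata.
- **Exposure and covariates**: sodium $\sim N(164.8, 37.9^2)$ mEq/day,
  age $\sim N(59, 11.8^2)$, BMI $\sim N(23.6, 3.6^2)$, 66.4% female,
  23.7% medicated, 20 standard-normal PC columns with no BP effect. The
  replication site shifts the age, sodium and BP means (+3.6 y, +11.8
  mEq/day, +3.3 mm Hg) to mimic a second recruitment region.
- **Blood pressure** follows the interaction model with residual SD 17.2
  (SBP) / 10.9 (DBP) plus an age effect (0.71 / 0.40 mm Hg per year) that
  brings the marginal SD to the observed ≈19.2 / 11.9 mm Hg; sex and BMI
  effects default to 0 but are knobs, since realistic effect sizes for
  them are not pinned down by the design. Two device measurements per
  trait are emitted (SD 2 mm Hg each); medicated subjects' measured BP is
  lowered by 10/5 mm Hg so that the preparation step's imputation is
  meaningful rather than a no-op.
- **Spot urine**: `gen_spot_urine()` inverts the sodium estimator exactly;
  its `noise_sd` is the log-scale SD of multiplicative noise on the
  estimate. With the default cohort (coefficient of variation of true
  sodium ≈ 0.23), `noise_sd = 0.3` gives an estimate–truth correlation of
  about $0.23/\sqrt{0.23^2 + 0.3^2} \approx 0.6$, bracketing the ≈0.54
  validation correlation reported for spot-urine estimators — i.e. the
  generator can emulate realistic exposure measurement error, though the
  primary analyses use the directly generated sodium.

What the generator does **not** emulate: linkage disequilibrium between
variants (each variant is independent, so multiple-testing behaviour over
correlated variants is untested), haplotype-level imputation error,
genotype–covariate confounding (PCs are pure noise here), non-Gaussian BP
residuals, and informative medication (medication is independent of BP).
Passing tests therefore demonstrate correctness of the estimators and
decision logic under the assumed model, not robustness to the
model-misspecification patterns of real cohort data.

## Numerical and degenerate-input choices

- Model fitting uses QR-based least squares (`lm.fit`); coefficient
  covariances come from the pivoted $R$ factor. Complete cases are taken
  per test, after the upfront exclusion of subjects missing core
  variables.
- A variant whose coded genotype is constant, whose interaction column is
  collinear with the design (e.g. constant exposure), or with fewer
  observations than parameters yields an `untestable` record — never an
  exception — so a genome-wide loop cannot be derailed by one degenerate
  variant. An all-missing variant likewise yields an all-fail QC row.
- The LRT is clamped at 0 against floating-point negativity; P-values are
  capped at 1. HWE probability ties are compared with a $10^{-12}$
  relative tolerance so analytically tied outcomes are included.
- Tertile boundaries are whole-cohort quantiles; boundary ties go to the
  lower tertile (deterministic, matching "<" boundary conventions).
  Displayed tertile means/SDs are raw, while the mean differences and
  their P-values come from an age-, sex-, BMI-adjusted linear model with
  tertile indicators — summaries describe the data, inference is
  adjusted.
- The hypertension odds ratio defaults to the unadjusted 2×2 with Woolf
  CI; a covariate-adjusted logistic path exists behind `adjusted = TRUE`.
  The low/high sodium strata default to a median split (`split` switches
  to outer tertiles); zero cells trigger the Haldane +0.5 correction with
  a warning.
- All generators are seeded and bit-reproducible: identical configuration
  and seed give identical cohorts, scans and reports.

## Problem sizes used by the test suite

The suite favours sizes that make the statistical checks sharp while
keeping a full run in minutes: power cells use the full $n = 4{,}527$ with
1,000 iterations; type-I error and genomic-control calibration use one
null cohort of 2,000 subjects × 10,000 independent variants;
$\beta_{GE}$ recovery uses 200 cohorts at full cohort size; the
end-to-end pipeline check uses 500 + 500 subjects × 200 variants with one
planted recessive interaction. The HWE oracle comparison is exhaustive for
$n \le 100$ and covers every allele configuration for $n \le 200$.

## Known limitations

- Cohort-derived association estimates (specific betas, subgroup means,
  inflation-factor ranges of any particular study) depend on restricted
  individual-level data and are not reproducible here; the synthetic
  cohorts validate the machinery, not those numbers.
- No LD-aware locus clumping: "independent loci" reduce to per-variant
  records because simulated variants are unlinked.
- Single-process scanning; at desk scale (10⁴–10⁵ variants) this is
  seconds to minutes, but a 7-million-variant scan would need chunked
  parallel execution around `genome_scan()`.
- The sodium estimator template assumes a positive predicted creatinine;
  coefficient sets that violate this are rejected rather than silently
  extrapolated.
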