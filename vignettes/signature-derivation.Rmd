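---
title: "Deriving and validating a knockdown-influenced prognostic signature"
author: "survSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a knockdown-influenced prognostic signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survSig)
```

# The workflow and its assumptions

`survSig` operationalizes a common translational design: genes whose
expression responds to silencing a regulator in vitro, and which are also
consistently dysregulated in tumors across several cancer types, are
aggregated into a signature whose weighted expression predicts
recurrence-free survival. The pipeline makes three modeling commitments:

* **Expression is analyzed on the log2 scale.** All statistics (SAM d,
  paired t, fold change, Cox covariates) assume approximately additive,
  roughly Gaussian behavior on that scale.
* **Survival follows proportional hazards.** The scoring weights, the
  validation fits and the resampling statistic are all Cox Wald
  statistics, meaningful only under (approximate) PH.
* **The scoring model is frozen on training data.** Weights Z_i and the
  standardization constants mu_i, tau_i are estimated once on the
  training cohort and never updated when a validation cohort is scored;
  a leak-free evaluation is the point of the freeze.

# Stage by stage

## Preprocessing

Probe-level detection calls are not available for a gene-level matrix, so
presence is redefined as a detection threshold on log2 values: a gene is
kept when at least `minFraction` (default 2/3, boundary inclusive) of
samples are at or above `detectionThreshold` (default: the cohort's 10th
percentile, a heuristic for "background"). This preserves the
selectivity contract of a detection-call filter without raw data.
"Unique annotation" is ambiguous between dropping all duplicated symbols
and collapsing them; strict dropping is the default because it matches
the narrow reading, and a `collapse` mode (keep the highest-mean row) is
provided. Chromosome dialects `chrX`/`X`/`23` are normalized before sex
chromosomes are removed; a missing chromosome annotation is an error
rather than a silent pass-through. Filters are idempotent, never touch
the sample dimension, and log a removal report in application order
(presence, dedup, sex chromosomes).

## Differential expression

For two-group knockdown contrasts the moderated statistic is
d_i = (mean2_i − mean1_i)/(s_i + s0), with s_i the pooled standard error
of the mean difference and s0 a fudge factor that keeps near-zero
variance genes from dominating the ranking. s0 defaults to a Tusher-style
selection: candidate percentiles of the s_i distribution are scored by
the coefficient of variation of mad(d) across s_i windows, and the
minimizer wins; with fewer than 10 genes the median of s_i is used.
q-values come from a balanced label-permutation null (default 1000
permutations, or exhaustive enumeration with a warning when fewer
distinct assignments exist): for each gene, q = pi0 × (median null
exceedance count)/(observed exceedance count), with pi0 estimated from
the fraction of observed d inside the central 25–75% quantiles of the
null and q monotonized so it never increases with |d|. Ties use the ">="
convention throughout. Significance requires both q < 0.05 and a
symmetric fold change max(FC, 1/FC) > 1.1, so down-regulation is treated
the same as up-regulation.

Paired tumor/normal designs use the classical paired t on per-patient
log2 differences with Benjamini–Hochberg adjustment (via `p.adjust`), and
by default no fold-change gate — the significance call there is adjusted
p < 0.05. Zero-variance differences are reported as infinite t with p = 0
(flagged), or t = 0, p = 1 when the differences are identically zero.
All tests are two-sided; directions are recorded separately.

## Signature derivation

Candidates are genes significant in *both* knockdown contrasts with equal
sign. Each tumor contrast then contributes one unit of support when the
gene is significant *and* its tumor direction satisfies the concordance
convention; support never goes negative for a significant-but-discordant
contrast. The convention ("same": tumor change matches knockdown change;
or "opposite") is a mandatory explicit argument because the biological
reading is genuinely ambiguous — a regulator elevated in tumors perturbs
its targets in the direction opposite to its knockdown. "same" is the
default reading of "concordant", and the synthetic study generator plants
tumor shifts aligned with the knockdown shifts so that the default
convention recovers the planted truth. Genes with support ≥ 3 (of 4
contrasts, by default) form the signature. Derivation is a pure function
of its inputs: rerunning with the same inputs yields the identical
signature, and relaxing `minSupport` can only grow it.

## Risk scoring

S = Σ Z_i (e_i − mu_i)/tau_i. Design choices worth stating:

* **mu/tau scope.** The standardization constants are frozen from the
  training cohort (the leak-free reading); a `standardize = "cohort"`
  mode re-standardizes within the scored cohort for sensitivity
  analysis, and its use is recorded on the result.
* **Missing genes at scoring time** drop their term without renormalizing
  the remaining weights, preserving each weight's meaning; dropped genes
  are reported.
* **SD uses the n−1 denominator**; tau must be strictly positive (zero
  variance genes are dropped at fit time with a warning).
* **Classification is strict**: positive means S strictly greater than
  the threshold — the median of the cohort being classified, or zero as
  an absolute cutoff (useful because the median score is close to zero
  in standardized cohorts). With all scores equal, nobody exceeds the
  median and all patients are negative.
* **Cox ties**: Efron by default, Breslow switchable (irrelevant for
  continuous simulated times).

## Survival analysis

Kaplan–Meier, log-rank and Cox PH go through the `survival` package;
`survSig` standardizes the interfaces and returns tidy HR/CI/p tables.
Non-convergence and monotone likelihood (complete separation) are
surfaced via a warning and a `converged` attribute. Stratified
re-analysis carries the *whole-cohort* risk classification into each
stratum (matching the way a fixed signature status is interpreted
clinically) rather than re-splitting per stratum; strata with a single
risk group or an event-free group are flagged unevaluable and skipped.
The 95% CI level is fixed.

## Resampling null

The non-randomness test draws size-matched random gene signatures from
the pool of genes shared by both cohorts (the tested genes are kept in
the pool by default; exclusion is a flag) and routes *every* draw through
the same function that evaluates the observed signature — fit weights on
training, score and median-split the evaluation cohort, take the Wald Z
of the positive-vs-negative Cox fit — eliminating any "tested
differently" bias by construction. Degenerate draws (a risk group
without events) are redrawn and counted. The right-tailed empirical p
uses add-one smoothing, p = (1 + #{Z_null ≥ Z_obs})/(1 + B), so p is
never zero and is bounded below by 1/(B+1). Weights are refit on the
training cohort for each draw by default, mirroring the observed
pathway; an in-cohort mode exists for sensitivity analysis.

## Enrichment

Over-representation uses the one-sided Fisher exact p, computed as the
hypergeometric upper tail at the observed overlap, with BH adjustment
across sets; both raw and adjusted p are reported so either reading of a
fixed significance line is available. The background universe is the
caller's choice; genes surviving preprocessing are the natural default.

# What the synthetic data do and do not emulate

The generators produce log2-scale Gaussian expression around per-gene
baselines: knockdown pairs add a signed shift to planted genes in the
knockdown arm; paired designs add a per-patient random intercept (which
cancels exactly in paired differences) plus a signed tumor shift;
survival cohorts draw Weibull event times whose hazard is proportional
to exp(Σ beta_g z_g) on cohort-standardized expression, censored by an
independent exponential process and an administrative horizon. Default
Weibull shape 1.2 and scale 60 months with censoring rate 1/80 per month
and a 120-month horizon give roughly 40% censoring at a null linear
predictor — a realistic recurrence-free survival profile. Clinical
covariates (age, sex, smoking, stage) are generated independently of
expression by default; a `covariateHazard` knob induces confounding when
wanted. A master seed fans out into named sub-streams per object, so
generating one more dataset never shifts another's draws.

Not emulated: probe-level hybridization noise, heavy-tailed or
platform-specific intensity distributions, batch effects, correlated
gene modules, and non-proportional hazards. Passing tests on this
synthetic world therefore demonstrate the *correctness of the
computations and the recoverability of planted truth under the stated
model* — not robustness to the full messiness of real cohorts.

# Numerical choices and degenerate inputs

* SAM denominators are floored at a tiny positive value when s_i + s0 is
  exactly zero, so d is always defined.
* The Cox partial likelihood is maximized by `survival::coxph` (its
  default convergence tolerances); the package's own independent checks
  use grid search and the score-test/log-rank identity.
* Median thresholds use R's default median (midpoint of the two central
  order statistics for even cohorts); the strict `>` rule decides
  patients sitting exactly at the threshold into the negative group.
* Presence-filter boundary comparisons include a 1e-12 slack so that
  fractions like 2/3 computed in floating point remain inclusive.
* Empty intersections, empty signatures, strata without both risk
  groups, and all-censored groups are all explicit, tested paths — they
  return empty/flagged results or errors, never silent garbage.

# Problem sizes used by the test suite

The packaged checks run at deliberately modest sizes chosen to make the
statistical assertions sharp but cheap: the end-to-end derivation uses
2000 genes with 40 planted signature genes (two 5-vs-5 knockdown arms,
four paired cohorts of 19–24 patients); SAM calibration uses 1000 genes,
5v5, 200 permutations; Cox recovery uses 50 replicates of n = 500;
resampling calibration uses 100 outer replicates of 99 resamples with
5-gene signatures over a 30-gene pool, and the demo determinism check
runs an 800-gene configuration twice. The full demo (`demoConfig()`)
uses 200 resamples; a production analysis would use 1000, as the
`nResamples` default of `randomSignatureNull()` does.

# Known limitations

* Signature genes are matched by symbol; cross-platform probe mapping is
  out of scope.
* No proportional-hazards diagnostics are included; the Cox summaries
  assume PH holds.
* The resampling null resamples genes, not survival labels — it answers
  "is this signature better than a random one of the same size?", not
  "is there any survival signal at all?".
* Multivariate covariate codings follow the phenotype table as given;
  the package does not re-derive clinical stage or grade groupings.
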