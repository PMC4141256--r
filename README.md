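# survSig

Derivation and survival validation of knockdown-influenced prognostic
gene-expression signatures.

## The problem

A recurring design in cancer transcriptomics: silence a regulator gene in
cell lines, collect the transcripts it perturbs, keep the ones that are
also consistently dysregulated across tumor-versus-normal comparisons in
several cancer types, and ask whether that gene set predicts patient
outcome. `survSig` implements this workflow end-to-end for R users —
bioinformaticians and biostatisticians who have gene-level log2 expression
matrices with phenotype/survival tables and want a tested, reproducible
pipeline rather than a pile of one-off scripts:

1. **Preprocessing** — matrix-level presence filtering (detected in at
   least two thirds of samples), unique-annotation deduplication, and
   removal of genes on chromosomes X and Y.
2. **Differential expression** — a SAM-style moderated statistic
   *d* = (mean₂ − mean₁)/(s + s₀) with label-permutation q-values for the
   small-n knockdown contrasts (significance: FDR < 0.05 and symmetric
   fold change > 1.1), and the classical paired t-test with
   Benjamini–Hochberg adjustment for tumor/normal designs.
3. **Signature derivation** — genes significant in both knockdown
   contrasts with concordant direction, then supported (significant and
   direction-consistent under an explicit concordance convention) in at
   least 3 of 4 tumor contrasts.
4. **Risk scoring** — per patient, *S* = Σᵢ Zᵢ·(eᵢ − μᵢ)/τᵢ, where Zᵢ is
   the Wald statistic (β̂/SE) of a univariate Cox regression of survival
   on gene *i* in the training cohort and μᵢ, τᵢ are the training mean
   and SD. The model is frozen after fitting; patients with *S* strictly
   above the cohort median (or above zero) are called risk-positive.
5. **Validation** — Kaplan–Meier curves, log-rank tests, univariate,
   multivariate and stratified Cox proportional-hazards models (Efron
   ties), reported as HR with 95% CI.
6. **Resampling null** — the signature's Cox Wald statistic compared
   against 1000 size-matched random gene signatures pushed through the
   identical scoring pipeline, with a right-tailed add-one empirical p.
7. **Enrichment** — Fisher's exact over-representation of the signature
   in user-supplied gene sets (GMT) against a background universe.

A synthetic-data module generates every input class with planted,
recoverable ground truth — small-n knockdown pairs, paired tumor/normal
matrices with a patient random effect, and Weibull proportional-hazards
survival cohorts with independent censoring — so the whole pipeline is
testable without any external download.

## Worked example

The demo configuration simulates the full study — 2000 genes, 40 planted
signature genes, two 5-vs-5 knockdown datasets, four paired tumor/normal
cohorts, and training (n = 150) / validation (n = 200) survival cohorts —
then derives and validates the signature:

```r
library(survSig)
res <- runPipeline(demoConfig(seed = 1))

res$signature
#> GeneSignature with 40 genes
#>   G0001, G0002, G0003, G0004, G0005, G0006, G0007, G0008, ...

res$riskValidation
#> RiskScores for 200 patients (median cutoff 0.08543): 100 positive

res$survival$validation$cox[, c("covariate", "HR", "ciLow", "ciHigh", "p")]
#>      covariate   HR ciLow ciHigh        p
#> 1 riskpositive 3.46  2.33   5.13 6.35e-10

res$resampling
#> ResamplingResult: observed Z = 6.181 vs 200 null draws, right-tail p = 0.004975
```

All 40 planted genes are recovered with no off-target members
(`res$recovery`), risk-positive patients relapse at a hazard ratio of
3.46 (95% CI 2.33–5.13) in the held-out cohort, and the signature beats
size-matched random signatures (right-tailed p ≈ 0.005 at 200
resamples). `runPipeline(cfg, outDir = "run1")` additionally writes every
stage output (signature TSV, frozen scoring model JSON, score/Cox/KM
tables, resampling null, manifest) deterministically: identical configs
give byte-identical run directories.

For real data, `readExpression()`, `readPhenotype()` and `readGMT()`
ingest tab-delimited matrices, phenotype tables (with `+`/`-` covariate
codings) and gene sets; `n39Signature()` loads the packaged 39-gene list,
and small toy input files live in `inst/extdata/`.

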