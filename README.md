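# prognosig

Discovery and evaluation of cut-off-based prognostic gene-expression
signatures from multi-cohort survival data, modelled on signature
development for stage II colorectal cancer — where roughly one in five
patients relapses after surgery and better risk stratification decides
who should receive adjuvant chemotherapy.

## What it computes

The pipeline has three phases:

1. **Multi-cohort survival screen.** For every gene *g* and cohort *c*,
   the optimal dichotomizing cut-off *x\*₍g,c₎* is the maximally selected
   log-rank statistic: over all admissible splits (each side holding at
   least a fraction `minprop = 0.1` of samples), choose the cut maximizing
   the standardized statistic |U|/√V, where U is the observed-minus-
   expected event count in the high-expression group over pooled risk
   sets and V its hypergeometric variance. A gene is a hit when its split
   is log-rank significant (α = 0.05) in at least `min_cohorts = 4` of
   the cohorts with a consistent direction (unfavorable = high expression,
   worse relapse-free survival). The cross-cohort replication rule, not a
   per-gene multiplicity correction, is the error control.

2. **Recurrence scoring.** Each signature gene contributes a 0/1 point
   per tumor: an unfavorable gene scores 1 strictly above its cut-off, a
   favorable gene strictly below. The integer recurrence score
   RS = Σ₍g∈sig₎ point(g) ∈ [0, |sig|]; a score cut-off (again maximally
   selected) classifies tumors high/low risk. The Oncotype DX colon
   comparator RS_U = 0.15·(BGN+FAP+INHBA)/3 − 0.3·(MYBL2+KI67+MYC)/3 +
   0.15·GADD45B is included, both as the linear formula and as a
   7-gene cut-off score.

3. **Beam-search refinement.** All 2-gene combinations from the candidate
   pool are scored by the log-rank p of their recurrence-score classifier;
   the top B (default 2000) are extended one gene at a time, keeping the
   top B at every size up to the pool size. The trace of per-size best p
   values picks the signature size k* = argmax −log10(p).

Supporting modules: per-gene z-score pooling of cohorts, two-step
NanoString nCounter normalization (positive-control then housekeeping
geometric-mean scaling) with an RLE/PCA outlier-sample QC and a
<10 counts/sample gene filter, evaluation reports (Kaplan–Meier, hazard
ratios, ROC/AUC with Youden operating points, binomial risk-of-recurrence
curves, multivariate Cox tables, signature-vs-signature concordance), and
a synthetic multi-cohort generator with planted proportional-hazards
effects that makes the whole pipeline testable without any download.

## Worked example

Simulate a six-cohort training suite (150 tumors each, 200 genes, 10 of
them planted with |log-HR| = 0.8 per SD), screen, pool, refine, evaluate:

```r
library(prognosig)

cfg <- simConfig(seed = 2026, n_cohorts = 6, n_samples = 150,
                 n_genes = 200, n_unfavorable = 6, n_favorable = 4)
suite <- simulateTrainingSuite(cfg)

screen <- screenAll(suite$cohorts, screenConfig(alpha = 0.05, min_cohorts = 4))
attr(screen, "summary")
#>   favorable unfavorable
#>           7          10
head(screen[, 1:4], 4)
#>    gene     verdict n_significant        min_p
#> 1 G0001 unfavorable             5 7.565360e-09
#> 2 G0004 unfavorable             5 6.755755e-08
#> 3 G0008   favorable             6 9.283443e-08
#> 4 G0005 unfavorable             6 1.041886e-07

hits   <- screen[screen$verdict != "excluded", ]
pooled <- poolCohorts(lapply(suite$cohorts, zscoreGenes))
trace  <- beamRefine(hits$gene, setNames(hits$verdict, hits$gene),
                     pooled, B = 200)
sel    <- selectSignatureSize(trace)
sel$signature
#> GeneSignature: 11 genes (6 unfavorable, 5 favorable)
#>   genes: G0001, G0002, ..., G0010, G0057

evaluateSignature(sel$signature, pooled)
#> Signature performance (RFS): HR = 8.31 (6.66-10.4), log-rank p = 6.07e-107
#>   AUC = 0.843; sensitivity 77.2%, specificity 76.5%, accuracy 76.8%
#>   n high/low = 195/705 (score cut-off 5.5)
```

The screen recovers the ten planted genes (17 hits total, 7 false
positives at this scale), and the refined signature contains all ten; the
high-score group's relapse hazard is 8.3-fold that of the low group, with
AUC 0.84 for predicting relapse. The risk of recurrence rises
continuously with the score (`riskOfRecurrenceCurve`, slope p ≈ 3e-31 on
this data).

Staged runs with manifests (`runStage("simulate" | "screen" | "refine" |
"score" | "evaluate" | "compare" | "normalize", config)`) and a thin CLI
wrapper (`inst/scripts/prognosig`) cover the same steps from config
files. The methods vignette (`vignettes/prognostic-signatures.Rmd`)
documents the statistical choices and the generator.

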