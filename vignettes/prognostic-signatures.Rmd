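---
title: "Methods: cut-off-based prognostic signature discovery"
author: "prognosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cut-off-based prognostic signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognosig)
```

## The problem

Stage II colorectal cancer sits in a treatment gray zone: most patients
are cured by surgery, but roughly 20% relapse within five years, and
adjuvant chemotherapy offers only a few percentage points of survival
benefit against substantial toxicity. A prognostic score that separates
high-relapse-risk from low-risk tumors at surgery would let treatment
concentrate on the patients who can benefit. This package implements a
complete discovery pipeline for such scores from multi-cohort
transcriptomic + survival data: a replication-based per-gene screen, an
integer recurrence score built from per-gene expression cut-offs, and a
beam-search refinement of the gene subset, together with the evaluation
battery (Kaplan–Meier/log-rank, hazard ratios, ROC, continuous risk
curves, multivariate Cox) and a NanoString nCounter normalization path
for targeted validation panels.

## Data model

Cohorts are `SurvCohort` objects — `SummarizedExperiment`s whose assay is
a genes × samples expression matrix on a platform-normalized scale
(log-intensity microarray, RSEM, or normalized counts) and whose
`colData` carries relapse-free survival (RFS: months to relapse, 0/1
event), optional overall survival, and clinical covariates (pT ∈ {3,4},
grade ∈ {1,2,3}, MSI/MSS, KRAS wt/mut, age, sex). Only samples with
complete expression and RFS data enter a cohort; all other fields may be
missing. Probe-level platforms are collapsed to gene level by summing all
probes of a gene (`collapseProbes`). For pooled analyses, each cohort is
first z-scored per gene (sample standard deviation, n − 1 divisor; genes
with zero variance carry no prognostic information and are dropped) and
cohorts are merged on the intersection of their gene sets
(`poolCohorts`), with sample ids prefixed by cohort for lossless
provenance. Intersection rather than union-with-imputation keeps every
pooled value an observed one.

## The maximally selected cut-off

Every stage dichotomizes a continuous quantity (a gene's expression, or
the integer recurrence score) at the cut-off maximizing the standardized
two-group log-rank statistic. For a candidate cut c, samples split into
high (x > c) and low; over the pooled risk sets the high group's
observed-minus-expected event count U(c) and its hypergeometric variance
V(c) give z(c) = |U(c)|/√V(c). The scan covers every midpoint between
consecutive sorted unique values whose split leaves at least `minprop`
(default 0.1) of samples on each side; ties in z are broken toward the
smallest cut-off, so the scan is fully deterministic. The selected
split's log-rank p value is reported as-is — the selection optimism this
carries is a property of the screening design itself, which controls
errors through cross-cohort replication rather than per-test calibration
(see below). The scan is exact, not sampled: an exhaustive-enumeration
oracle in the test suite verifies the argmax on every fixture. The core
is implemented in C++ (`src/maxsel.cpp`); for integer scores all cut-offs
are evaluated in a single sweep over event times using suffix sums over
score values, which is what makes beam search over thousands of
combinations tractable on one CPU.

## Per-gene screening across cohorts

`screenAll` computes, for every gene in the cohorts' shared gene universe
and every cohort: the optimal cut-off, the log-rank chi-square and p of
the induced split, and the direction (unfavorable when the
high-expression group has more events than expected, favorable
otherwise). A gene receives a verdict when it is significant at `alpha`
(default 0.05) in at least `min_cohorts` (default 4, of a six-cohort
design) cohorts **and** all significant cohorts agree in direction;
otherwise it is excluded. Direction consistency is required because a
"prognostic" gene whose effect flips sign between cohorts is not usable
in a fixed-direction score; with it, the chance that a pure-noise gene
survives the rule is below 2% per gene at the default settings (the
4-of-6 replication bound times the probability that four independent
directions agree), which the null-simulation tests confirm empirically.
No multiple-testing correction is applied across genes — replication is
the error control — and this is deliberate and documented rather than
hidden.

## Recurrence scores

Given a signature (genes with fixed directions), each gene contributes a
0/1 point per tumor relative to its cohort-specific cut-off: unfavorable
genes score 1 strictly above the cut-off, favorable genes strictly below.
Expression exactly at the cut-off scores 0 under either direction — the
conservative convention, and a measure-zero event for continuous data.
The recurrence score is the sum over signature genes, an integer in
[0, |signature|]; high scores mean high expression of unfavorable genes
and low expression of favorable ones. Cut-offs are recomputed per cohort
by default (each platform has its own scale); `trainCutoffs` freezes them
into the signature for application to new samples, and the score cut-off
for high/low classification can be frozen the same way. The 15-gene
signature definition (nine unfavorable: BET1L, CD2BP2, CD40LG, JUP,
KCND2, SNAPC5, TMEM86B, TRIP10, ZNF785; six favorable: ATOH1, FAM173B,
GGT6, MTF1, TBC1D3H, UNC13B) and the 7-gene Oncotype DX colon set ship as
JSON files under `inst/extdata`. For the Oncotype comparator, the linear
RS_U formula is evaluated exactly as published, and a cut-off-based
variant applies this package's scoring with directions from the RS_U
coefficient signs (BGN, FAP, INHBA, GADD45B unfavorable; MYBL2, KI67,
MYC favorable); KI67 is resolved to the official symbol MKI67 through a
small alias table.

## Beam-search refinement

The search space of gene subsets is far too large to enumerate (2⁶¹ for
a 61-gene pool), so refinement uses a beam: evaluate all C(G,2) pairs by
the log-rank p of their recurrence-score classifier, keep the top
B = 2000, then repeatedly extend every retained combination by each
remaining pool gene, deduplicate extensions by set identity, and keep the
top B per size until the pool is exhausted. Per-gene cut-offs are fixed
once per cohort (they depend only on the gene), while the score cut-off
is re-optimized for every combination, mirroring per-signature
classification. Ordering is by p ascending, then chi-square descending
(separating combinations whose p underflows), then lexicographic gene
order — so a rerun is byte-identical. `selectSignatureSize` picks
k* = argmax −log10(p) over the per-size trace, smallest k on ties,
favoring the more parsimonious signature. Two design points were
genuinely open: duplicate combinations reached by different extension
paths are merged (the search is over subsets, not paths), and the beam is
truncated to B at *every* size; the alternative reading — prune only once
at size 2 — is available as `prune_once = TRUE`. Beam search is a
heuristic: with B = ∞ it provably equals exhaustive enumeration (the
tests verify this exactly for pools up to 10), but at finite B no global
optimality is guaranteed, exactly as in the original three-phase designs
this emulates.

## Evaluation battery

`evaluateSignature` reports, per cohort and endpoint (RFS or OS): the
two-group hazard ratio with Wald 95% CI from a Cox fit on the high/low
label (Efron tie handling — scores are heavily tied integers), the
log-rank p, and the ROC of the integer score against relapse labels
(relapse-ever by default; a relapse-by-horizon variant excludes samples
censored earlier). AUC is the pairwise concordance probability with ties
counting ½; the reported sensitivity/specificity sit at the
Youden-optimal threshold (the operating-point convention adopted here,
reported alongside, since marked thresholds on published ROC curves
rarely state their rule), and accuracy is (TP+TN)/n at that same point.
`riskOfRecurrenceCurve` fits a binomial GLM of relapse-by-horizon
(120 months, i.e. ten years) on the score; samples censored before the
horizon without an event are uninformative for the horizon-restricted
outcome and are excluded — a choice that trades a small selection effect
for model simplicity and is stated rather than silent.
`multivariateReport` produces the clinical-table-style joint Cox fit
(signature high/low adjusted for pT 4-vs-3, grade 3-vs-1+2, MSS-vs-MSI,
complete cases only), `combinedPtStratification` the four-group
signature × pT Kaplan–Meier comparison with within-stratum log-rank
contrasts, and `compareSignatures` the patient-by-patient high/low
concordance of two signatures plus their high-risk count difference (how
many patients one score would spare from a high-risk call).

## NanoString normalization and QC

Raw nCounter-style counts are normalized in two multiplicative steps,
both using geometric means (lane effects are multiplicative, and the
geometric mean is the standard for control-based count normalization):
first each sample is scaled so its positive-control geometric mean equals
the grand geometric mean across samples (removing hybridization/lane
variation), then likewise on the six housekeeping genes (AKAP1, DNAJC14,
SF3A1, TBC1D10B, TKL2, TMUB2 — the panel is overridable; "TKL2" is kept
as printed in the source panel although the official symbol is likely
TLK2), after which only endogenous probes are returned. Zero control
counts are replaced by 0.5 before the logarithm; nonzero counts are left
untouched, so the exact multiplicative scale relations hold — scaling a
sample's raw counts by c changes its normalized profile only by the
common grand-mean factor c^(1/n), which the tests verify to 1e-9. (An
additive pseudo-count on all control counts would break that exactness,
which is why zero-replacement was chosen.) Genes averaging below
10 counts/sample (strict inequality) are filtered with a report.
Sample QC flags dispersed profiles by relative log expression — a
sample's log2 ratios to gene-wise medians — and principal components:
a sample is excluded when its RLE median or RLE IQR, or its PC1/PC2
coordinate, lies more than 3.5 robust (MAD-based) deviations from the
cohort center. The 3.5 threshold is a conventional robust-outlier choice;
on small panels (a few dozen samples) the MAD of tightly clustered RLE
medians can be small enough that a borderline normal sample is flagged,
so the threshold should be read as a screening default, not a calibrated
error rate.

## The synthetic generator

`simConfig`/`simulateTrainingSuite` generate the study conditions all
tests run under: six cohorts of 150 tumors, 520 genes of which 20 carry
proportional-hazards effects on relapse (12 unfavorable, 8 favorable,
|log-HR| 0.8 per SD of expression). Expression is standard normal per
gene (the biological signal) plus cohort-specific per-gene location
shifts (SD 0.5) and a cohort-wide scale factor (U(0.7, 1.4)) — batch
structure that per-cohort z-scoring removes by construction. The relapse
hazard is exponential, λᵢ = λ₀·exp(Σ βg·zᵢg + βpT·1[pT4]) with
λ₀ = 0.004/month (≈21% relapse by five years, the realistic stage II
rate), pT4 prevalence 0.2 and βpT = log 2.4 (typical reported pT effect);
censoring is the minimum of a 120-month administrative horizon and
exponential dropout (rate 1/150 per month, median follow-up ≈ 9 years).
OS shares the relapse linear predictor attenuated by 0.6 plus a normal
frailty (SD 0.5), so OS effects are real but weaker, as observed in
practice. The hazard acts on continuous expression, not on a
dichotomized version — deliberately, so the cut-off machinery is tested
against a smooth truth rather than against its own discretization. The
NanoString block draws negative-binomial counts (size 20) around gene
means log-uniform on [30, 2000], with nine planted low-expression genes
(means on [1, 8]), log-normal lane factors (SD 0.3) applied to all probe
classes, a fixed positive-control dilution series, and five planted
outlier samples whose endogenous counts get extra log-normal dispersion
(SD 1.5). Every quantity is reproducible from (config, master seed);
per-cohort seeds derive deterministically from the master.

What the generator does **not** emulate: real platforms' heavy-tailed and
gene-correlated expression, non-proportional hazards, informative
censoring, cohort case-mix differences, or the marginal distributions of
any particular public cohort. Passing tests therefore demonstrate that
the pipeline's machinery is correct and well calibrated under its own
stated model — not that any particular gene list is prognostic in real
tumors, and reproduction of cohort-specific published statistics is
explicitly out of scope (it would require external downloads and
undeposited data).

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so a
full run stays comfortably in minutes on one CPU: screens over
6 × 150 samples × 520 genes, ten replicate seeds for recovery rates,
beam width 200 over a 61-gene pool (pooled n = 900), 100–200 replicates
for estimator calibration, and exhaustive-enumeration oracles restricted
to pools of ≤ 10 genes where C(G,k) enumeration is exact and cheap.
Numerical conventions worth knowing: the log-rank variance uses the
ties-corrected hypergeometric form (factor (n−d)/(n−1)); z-scores use the
sample SD; cut-off scans require ⌈minprop·n⌉ samples per side; constant
score vectors are classified as uninformative (p = 1, flagged) rather
than erroring inside the search; Cox fits flag non-convergence,
singularity and separation instead of failing; and all high/low
orientation is fixed (high = strictly above the cut) so no result depends
on label order. Known limitations: the naive post-selection log-rank p
values are optimistic (by design, inherited from the screening
paradigm); the beam search offers no optimality guarantee at finite
width; and the QC thresholds are screening defaults rather than
calibrated false-positive rates.

## A minimal run

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1, n_cohorts = 6, n_samples = 150,
                 n_genes = 200, n_unfavorable = 6, n_favorable = 4)
suite <- simulateTrainingSuite(cfg)
screen <- screenAll(suite$cohorts)
hits <- screen[screen$verdict != "excluded", ]
pooled <- poolCohorts(lapply(suite$cohorts, zscoreGenes))
trace <- beamRefine(hits$gene, setNames(hits$verdict, hits$gene),
                    pooled, B = 200)
sel <- selectSignatureSize(trace)
evaluateSignature(sel$signature, pooled)
```
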