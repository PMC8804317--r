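---
title: "Classifying pathogenic cancer somatic SNVs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pathogenic cancer somatic SNVs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvpath)
```

This vignette is the package's account of its science: the labeling model
and its assumptions, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, the numerical choices, and the
design decisions taken where the method left room.

## The labeling model

The package treats driver/passenger discrimination as supervised
classification, which stands or falls with the label construction.

**Positives (pathogenic).** A somatic SNV is labeled positive when it
clears a *bi-dimensional recurrence threshold*: carrier frequency — the
number of distinct samples carrying the variant across the catalog — at
least $f$, and occurrence in at least $c$ distinct cancer types. The
second dimension encodes the clinical heuristic that a variant implicated
across multiple cancers is more credibly functional than one recurring in
a single context. Before thresholding, every variant also observed in
healthy individuals is excluded. The assumption being made is that
recurrence across patients and cancer types is driven by selection rather
than by mutational hotspots or mapping artifacts; at catalog scale that is
an approximation, and the threshold pair is the knob controlling how
conservative it is.

*Frequency counts distinct samples, not raw rows.* Catalogs contain
duplicate submissions of the same (variant, sample) observation; counting
rows would let submission practices leak into labels. Both readings are
consistent with how such a score is usually described; distinct-sample
counting is the robust one and is what `count_recurrence()` implements.

*Threshold selection.* "Enough training examples with minimal bias" is
formalized in `select_recurrence_thresholds()` as: among all cutoff pairs
retaining at least `min_positive_count` variants, maximize $f$, then $c$ —
the strictest filter that preserves the requested training-set size.
Raising a cutoff only removes variants (the threshold grid is monotone
non-increasing in both axes), so this scan is well defined. The shipped
defaults are $(f, c) = (4, 2)$ for coding and $(3, 2)$ for non-coding
variants, the catalog-scale operating points for this method.

**Negatives (benign somatic).** A variant is negative when its minor
allele frequency is at least 1% (inclusive, per "equal or greater") in at
least one reference population *and* it belongs to the catalog's
healthy-flagged somatic set. The intersection matters: the
population-frequency mixture alone contains germline variants, and the
healthy-somatic set alone contains rare variants of unknown status; only
the overlap is confidently benign *and* somatic. Positives and negatives
are disjoint by construction; a key qualifying for both under non-default
configurations is dropped and counted in provenance rather than
arbitrated.

## Features and imputation

The default schema (`default_schema()`) has 65 features shared by coding
and non-coding variants plus 15 coding-only ones, in four groups:
structural/genomic context, epigenetic, genomic distance, and
conservation. Five context/distance features are computed from sequence
and catalog; the remainder are *declared* as named annotation-track
placeholders because they are pre-aggregated products of external
annotation pipelines (ENCODE-style histone levels, CADD/VEP-style scores,
PolyPhen/SIFT) that it would be wrong to re-derive. The schema is an
ordinary tibble and is the single point of truth: matrices follow its
column order, and model artifacts fingerprint it.

Computed-feature conventions:

* "±75 bp window" means 151 bases centered on the variant, clipped at
  contig ends (with a warning, not an error).
* CpG content is the CpG-dinucleotide percentage in that window
  (overlap-free scan, denominator `length − 1`). A full CpG-island caller
  is deliberately not implemented; at a 151-bp scale the dinucleotide rate
  is the standard proxy.
* Rare-neighbor density counts distinct variants within ±100 bp with MAF
  strictly below 0.05, excluding the query; absence from the frequency
  table counts as rare.
* GC% excludes `N` bases from the denominator; an all-`N` window is a
  missing value.

**Imputation** (`mice_impute()`) is chained-equation, hand-implemented on
`lm.fit`/`glm.fit`: initial fill by column mean (continuous) or mode
(binary); then, per sweep, each originally incomplete column is regressed
on all other columns over its observed rows and its missing cells replaced
by predictions. Ten sweeps by default. It is *single* imputation — the
classifiers consume one completed matrix, and no pooled inference is done
that would require multiple draws. Two modes exist: `"stochastic"`
(default; seeded residual noise for continuous columns, Bernoulli draws
for binary ones, avoiding the variance shrinkage of pure regression
imputation) and `"deterministic"` (pure predictions; used by recovery
tests and anywhere a point estimate is wanted). Binary columns always come
back in {0, 1}; observed cells are never modified; a fully missing column
is an error rather than a guess. Logistic fits that fail (e.g. complete
separation) fall back to a clipped linear fit.

## Classifiers

**Standardization.** Features are centered and scaled by training-set mean
and *population* standard deviation (the sklearn `scale` convention);
constant columns map to zero and are flagged. Held-out data is always
transformed with training statistics — `apply_scaler()` refuses mismatched
column sets, and cross-validation refits the scaler inside each fold.
Normalization chiefly matters for the SVM, whose kernel distances would
otherwise be dominated by wide-scaled features.

**Lasso logistic.** `glmnet` fits the L1 path; the penalty is chosen by
10-fold cross-validated deviance with the `"1se"` rule (sparsest model
within one standard error of the minimum) as default, the usual parsimony
convention when the model doubles as a feature selector. `"min"` is
exposed. `tidy()` on the artifact returns the coefficient table with
|coefficient| ranks — zero coefficients are the discarded features.

**RBF-SVM.** No SVM implementation is available in the package's
dependency environment, so the dual problem is solved by an own SMO
implementation (compiled, LIBSVM-style second-order working-set
selection, stopping when the maximal KKT violation drops below
`eps = 1e-3`). Defaults are $C = 1$ and $\gamma = 1/p$ on standardized
inputs (the "scale" convention); they are deliberately not tuned per fit —
kernel and hyperparameter choice for this problem class is a trial-and-error
matter, and a fixed, documented default keeps cross-validation honest and
fast. Decision values are mapped to probabilities by a Platt sigmoid
(Newton's method with backtracking) fitted on *out-of-fold* decision
values from an internal 3-fold split of the training data, so the
calibration never sees the scores of the model it calibrates;
resubstitution calibration is available via `calibration_folds = 0`.

**Evaluation.** Two routes, mirroring standard practice: a stratified
2/3–1/3 train/test split (largest-remainder apportionment keeps class
proportions within one sample) and stratified 10-fold cross-validation in
which every sample is scored exactly once by a model that never saw it.
`roc_and_auc()` sweeps the rule "probability ≥ threshold" over distinct
scores, grouping ties; the trapezoidal AUC then equals the Mann–Whitney
concordance probability with ties counted one half, which the tests
exploit as an independent oracle.

**Operating threshold.** `select_operating_threshold()` returns the
*highest* threshold whose TPR reaches the target (default 0.80): among
all thresholds achieving the target sensitivity, the highest minimizes
the FPR. Calls at the threshold use ≥, so a probability exactly at the
cutoff is positive. Whether the threshold is chosen on pooled CV scores
or on the held-out third is left to the caller — both score vectors are
available; the staged pipeline uses held-out scores, and the acceptance
checks verify that a threshold chosen on training-side CV scores
transfers to the held-out third.

## Cohort screening

Cohort variants are scored and called at the region default thresholds
(0.55 coding / 0.41 non-coding — the catalog-scale operating points at
target TPR 0.80), overridable for stricter call sets. Downstream:

* recurrent positives: distinct-carrier count ≥ 4 (coding) / ≥ 2
  (non-coding), consistent with the gold-standard counting;
* gene status: a gene is mutated in a patient iff ≥ 1 predicted-pathogenic
  SNV — binary, not a burden count;
* candidate genes: ≥ 4 / ≥ 2 distinct pathogenic SNVs per gene;
* age-stratified screens: carrier vs non-carrier log-rank (survival
  package; hypergeometric variance, so tied event times are exact) within
  young (< 45) and old (≥ 45) strata, once per endpoint (OS/DSS/DFS)
  present. A unit is *young-specific* iff $p_{young} < \alpha$ and
  $p_{old} \ge \alpha$ with $\alpha = 0.05$. Strata with no carriers, no
  non-carriers or no events are reported not-evaluable and never flagged.
  Raw p-values are the default — the screening convention here reports
  uncorrected p at 0.05 — and a Benjamini–Hochberg option exists but is
  off.

The age cutoff (45 years), alpha, thresholds and minima are all plain
arguments.

## The synthetic world

The generators exist so that every stage is testable with known truth;
their defaults are a stated world, not a tuning surface.

* `simulate_catalog()`: ~10% drivers with carriers $= 4 + \mathrm{NB}(\mu
  = 4, \theta = 2)$ spread over ≥ 2 cancer types (never healthy-flagged);
  passengers with $1 + \mathrm{Poisson}(0.2)$ carriers; 25% of passengers
  healthy-flagged with max population MAF ≥ 0.01 (the true benigns). The
  shifted negative binomial reproduces the heavy-tailed recurrence the
  bi-dimensional filter exploits; it claims no mutational-process realism.
  Variant keys are sampled without replacement from (contig, position)
  slots, so keys never collide at any catalog size.
* `simulate_feature_matrix()`: informative continuous features are
  class-shifted Gaussians (default $d = 1.5$ SD on 10 of 80 columns),
  binary features Bernoulli(0.3), everything else standard-normal noise;
  missingness is MCAR at 10%. Real annotation features are correlated,
  non-Gaussian and not missing at random — a green test here establishes
  that the pipeline machinery recovers a planted signal, *not* that any
  particular AUC is attainable on real catalogs.
* `simulate_survival_cohort()`: exponential event times, hazard 0.02/month
  multiplied by HR 3 for young carriers (HR 1 for old), independent
  exponential censoring at ~30%, ages uniform within bands. Real cohorts
  have non-proportional hazards and informative censoring; the generator
  only plants the young-specific pattern the screen must detect.

Reference sequence is i.i.d. ACGT with GC bias 0.41 (the genome-wide GC
fraction) — sufficient for window features, with no genome structure.

## Numerical choices and degenerate inputs

* SMO: stopping tolerance 1e-3 on the KKT violation, curvature floor
  1e-12, iteration cap 200,000; intercept from free support vectors,
  midpoint of bounds if none.
* Platt: Newton with step-halving on the cross-entropy, the numerically
  stable log1p formulation, priors-adjusted targets.
* Ties in ROC scores are grouped into single thresholds; ties in event
  times use the hypergeometric variance.
* Constant feature columns: scaler maps them to 0; imputation drops them
  as predictors.
* One-class labels, empty survival groups, zero events, fully missing
  columns, single-column matrices, malformed variant keys and MAFs outside
  [0, 1] are errors with named offenders, not silent repairs.
* All stochastic operations take explicit seeds; identical seeds give
  bit-identical outputs (imputation included).

## Known limitations

* The full 80-feature inventory beyond the named computed features is a
  set of named placeholders; users supply real annotation tracks to fill
  them. External predictor scores are consumed, never recomputed.
* Catalog-scale results (database gold-standard sizes, AUCs near 0.9+ on
  real data, specific cohort counts) require licensed variant databases
  and are out of scope; nothing in the test suite claims them.
* The SVM has no class-weighting and the Lasso no elastic-net mixing;
  both would be natural extensions.
* Survival screening is log-rank only — no Cox modeling, hazard-ratio
  estimation or competing risks — and gene-set enrichment of candidate
  genes is out of scope (it depends on external services).
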