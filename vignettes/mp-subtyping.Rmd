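---
title: "Mesenchymal-phenotype subtyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesenchymal-phenotype subtyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsubtype)
```

`mpsubtype` implements a complete discovery-to-validation workflow for a
two-subtype (mesenchymal vs epithelial, MP/EP) structure in bulk
gastric-cancer expression cohorts. This vignette is the package's own
account of the statistical machinery: what each stage assumes, which knobs
matter, what the synthetic generator does and does not emulate, and where
the design was genuinely open and a choice had to be made.

## 1. Preprocessing

Expression matrices are genes × samples with an explicit scale flag
(`log2` / `linear`); every operation checks the flag, which rules out the
classic double-log and log-of-log2 accidents at the type level.

* **Quantile normalization** forces all samples onto the across-sample mean
  of the order statistics. We delegate to `limma::normalizeQuantiles`
  (ties averaged), the standard implementation for arrays. Genes with any
  missing value must be dropped first (`drop_incomplete_genes()`); we
  prefer an explicit refusal over silent imputation.
* **Variation filter**: keep gene *g* iff at least `min_samples` (default
  15) samples deviate from the gene's median by at least `log2(fold)`
  (default `fold = 2`, i.e. 1 log2 unit). Both boundaries are inclusive
  ("at least"). The twofold rule is interpreted on the log2 scale by
  default because the clustering display scale is log2 relative to the
  median; a linear-ratio interpretation is selectable via
  `interpretation = "linear"`.
* **Median centering** subtracts each gene's median (idempotent); it is the
  display convention behind "relative to the median across tissues" and
  stabilizes correlation-based clustering.

## 2. Subtype discovery

Agglomerative clustering of samples with centered Pearson correlation
distance (1 − *r*) and average linkage — the classic Cluster 3.0
configuration — cut at *k* = 2. The software lineage of this analysis
names the tool, not the settings, so both distance and linkage are
arguments. Conventions:

* the **smaller** tumor cluster is S = MP, the larger L = EP;
* an exact size tie is broken deterministically: the cluster containing the
  lexicographically smallest tumor sample id is S;
* outgroup (GIST-like) samples participate in the clustering — their
  co-segregation with MP is part of the biological argument — but never
  receive an MP/EP label and never count toward cluster sizes;
* samples are sorted by id before distance computation, making the result
  invariant to input column order.

## 3. Signature derivation (two-list rule)

Per-gene two-sample *t*-tests use the **pooled-variance** form by default
(the BRB-ArrayTools default for class comparison); Welch is selectable.
Genes with zero pooled variance are flagged and given *t* = 0, *p* = 1.
The signature is

> X ∩ Y restricted to |mean MP − EP log2 difference| ≥ log2(fold),

where X = genes with *p* < 0.001 for MP vs EP and Y = genes with
*p* < 0.001 for MP vs non-tumor tissue. Design choices:

* **No multiplicity correction.** The workflow deliberately uses a raw,
  stringent *p* < 0.001 on both lists; the consequence (expected
  G × 10⁻³ false positives per list, far fewer after intersection and fold
  filter) is documented rather than "fixed", because the published rule is
  part of what this package reproduces.
* The fold filter applies to the MP-vs-EP contrast only — that contrast
  defines the signature's downstream use. Its scale (log2 difference of
  means vs ratio of linear means) is parameterized (`fold_scale`).
* Signature weights are the MP-vs-EP *t*-statistics; their signs equal the
  fold-change signs by construction, which tests assert.

## 4. The Bayesian compound covariate predictor

Training computes per-gene standardization (mean, sd over training tumors),
the compound covariate *c* = Σ *t*<sub>g</sub> *z*<sub>g</sub>, per-class
means of *c*, a pooled within-class sd (classical compound-covariate form;
unequal variances selectable), and priors. Posteriors are Gaussian; the
computation runs in log space so samples far from both class means do not
underflow. A posterior of exactly 0.5 is called MP (deterministic tie rule).

Open choices, and what we picked:

* **Priors** default to 0.5/0.5. Empirical class frequencies are available
  (`priors = "empirical"`), but equal priors keep training-set prevalence
  assumptions out of validation cohorts, whose MP fraction is unknown.
* **Cross-cohort standardization.** When a signature trained on one array
  platform is applied to another, each validation cohort is gene-wise
  z-scored against its *own* means and sds (`standardize = "cohort"`);
  this is the simplest platform harmonization consistent with applying one
  signature across different chips. For single left-out samples (LOOCV)
  the model's training standardization is used — a one-sample cohort has
  no usable sd.
* **Missing signature genes** in a validation cohort: if ≤ 20% are absent
  they are dropped with a warning; more is an error. Under z-scoring,
  dropping a gene is algebraically identical to mean-imputing it (its z
  would be 0), so no separate imputation path exists.
* **LOOCV** re-derives the signature and re-trains inside every fold by
  default (honest CV). Folds receive a matrix view lacking the held-out
  sample, so selection can never touch it. The optimistic variant
  (`in_fold_selection = FALSE`) is exposed because the original
  description is silent about it and the difference is instructive. A fold
  whose in-fold signature comes back empty falls back to the fold's
  majority class and is counted in the report.
* The **reference classifier** for concordance is a linear SVM
  (`e1071::svm`, fixed cost 1, no internal scaling) on the same signature
  genes; it exists only to compute Cohen's κ against the BCCP. κ uses the
  Fleiss large-sample standard error under H₀ for its test; the
  both-raters-constant case (p<sub>e</sub> = 1) is reported as undefined
  rather than silently 0 or 1.

## 5. Survival analysis

Kaplan–Meier, log-rank, and Cox models delegate to the `survival` package
behind thin interfaces that standardize what the pipeline reports:

* **Ties** default to Efron (more accurate); Breslow is available, and the
  test suite uses it to assert the identity "two-group log-rank = Cox
  score test" numerically.
* **Inference**: Wald 95% CIs on the log-hazard scale, but the headline
  p-value everywhere is the likelihood-ratio test, matching the reporting
  convention of the analysis this package reproduces.
* **Convergence**: relative partial-likelihood tolerance 1e-9, at most 50
  iterations.
* Survival-at-*t* queries beyond a group's last observed time return the
  last step value and are flagged `extrapolated`.
* The **interaction analysis** fits RFS ~ subtype + chemo + subtype×chemo
  + sex + age + stage on the stage II–IV, no-distant-metastasis subset; the
  interaction p is the LRT of the product term. Stage enters as ordered
  numeric 1–4 by default (categorical selectable): with four sparse levels
  in a ~200-patient subset, the one-degree-of-freedom trend coding is the
  stabler adjustment. Per-subtype chemo HRs come from stratified
  single-covariate fits, mirroring the per-subtype Kaplan–Meier view.

## 6. Stromal content

Tumor fraction is estimated per sample by single-parameter constrained
least squares, observed ≈ p·tumor + (1−p)·normal on the **linear** scale
(physical mixtures of transcripts add linearly), with the closed form
p = ⟨y − n, t − n⟩ / ‖t − n‖² clipped to [0, 1]. With exactly two
reference profiles (mean tumor, mean surrounding tissue) this is
identifiable and dependency-free; it is a deliberate stand-in for
support-vector-regression deconvolution frameworks, not a reimplementation
of one. Histology-derived fractions can be supplied directly.

Two adjustment rules ship, because the published multiplication rule —
multiply linear expression by p — is not a mathematical removal of the
stromal signal: `as_published` reproduces it literally, and `model_based`
inverts the mixture ((obs − (1−p)·normal)/p, floored at 0, skipping
samples with p < 0.05 where the division is unstable). The discrepancy is
documented, not resolved; tests assert that planted subtype contrasts keep
their *sign* under model-based adjustment, the form in which the original
"not substantially changed" claim is checkable on synthetic truth.

## 7. Cross-cohort selection

A gene is conserved iff *p* < 0.001 in **every** cohort *and* its MP−EP
direction is identical in every cohort; direction consistency is on by
default and configurable, since the published description ("upregulated or
downregulated in all five cohorts") implies it without stating the check.
Gene universes are harmonized by uppercased symbol; the conserved set
shrinks monotonically as cohorts are added (asserted as a property test).
Mutation-rate comparisons run on the raw scale by default to match the
quoted Student's *t*-test, with a log10 option for heavy tails; the
hypermutation boundary is strict (> 11.4 mutations/Mb, a rate exactly at
the threshold is not hypermutated).

## 8. The synthetic generator

`generate_cohort()` emulates exactly the structure the analysis assumes:

* a log2-normal baseline per gene (mean 7, sd 1), a tumor-vs-normal offset
  (sd 0.5) on non-signature genes;
* **planted signature genes** (m, half up/half down in MP) shifted ±δ/2
  per subtype around a baseline equal to the normal profile — signature
  genes are subtype markers, not global tumor markers, which is the
  premise of the two-list rule;
* **stromal contamination**: each tumor is mixed with the normal profile
  on the linear scale at tumor fraction p ~ Beta(α, β), then re-logged;
  at p = 1 the expected value is the tumor profile exactly;
* **outgroup** samples carrying the MP-direction shifts at 1.5×δ, pure
  (p = 1), so they co-cluster with MP;
* an additive per-cohort, per-gene **batch shift** drawn once (sd
  `batch_shift_sd`) — the simplest structure that makes per-cohort
  standardization in the classifier matter;
* **survival**: exponential RFS with log-hazard
  log(hr_mp)·1[MP] + log(hr_chemo_subtype)·1[chemo]; independent
  exponential censoring shared by both endpoints; OS = RFS + an
  independent exponential post-recurrence time for event cases, so
  RFS ≤ OS holds sample by sample;
* **methylation** β-values linear in log2 expression with negative slope,
  centred at 0.5, clipped to [0, 1]; **mutation rates** log-normal with a
  subtype-specific meanlog.

Determinism: one master seed; each cohort (and each of its clinical,
methylation and mutation streams) seeds its own substream through a
counter-based scheme, so cohorts are independently reproducible in any
generation order.

**Default condition** (one-time choices, in log2 units and years): three
cohorts of 90 tumors, G = 2000 genes, m = 50 signature genes, MP prevalence
0.35, δ = 3, gene noise sd 1, batch sd 0.3, 20 normals and 3 outgroup
samples per cohort, tumor fraction ~ Beta(6, 2) (stromal content roughly
0–65%, matching the 0–72% range reported for real cohorts), baseline
hazard 0.15/yr, hr_mp = 2, hr_chemo = 0.45 (EP) vs 1.0 (MP), 60% treated,
censoring rate 0.05/yr. δ = 3 with ~30% average stromal dilution leaves an
observed subtype contrast of roughly 2 log2 units — the order of magnitude
the published fold-change filter presupposes; a δ at the filter boundary
would make the default demonstration dominated by the stromal-attenuation
artifact rather than the pipeline.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: probe-level microarray artifacts and
platform-specific probe sets; correlated gene-gene noise (genes are
conditionally independent, so clustering and LOOCV are easier than on real
arrays); non-proportional hazards and stage-dependent hazards; MSI/EBV
status; confounding between treatment assignment and prognosis (chemo is
randomized by `chemo_assignment_prob`, unlike retrospective clinical data).
Recovery rates and error bounds established on this generator are
best-case statements about the implementation's correctness, not about
clinical performance.

## 9. Problem sizes in the test suite

The suite verifies oracle equivalences on small exact instances (n = 6 Cox
brute force, 8-sample exhaustive log-rank permutations), calibration on
1000 null replicates at n = 200–300, parameter recovery at n = 500 with
500 replicates (hazard ratio), 200 mixtures (deconvolution), 100 samples
per arm with 2000 genes (signature recovery ≥ 45/50 planted at δ = 2,
sd = 1), and honest LOOCV at n = 100 (≤ 5% misclassification at δ = 3).
These sizes were chosen to make each check's sampling band informative
while keeping the full suite around a minute on one CPU.

## 10. Known limitations

* The exact BCCP variant inside BRB-ArrayTools is not published beyond its
  name; we implement the classical compound covariate with Gaussian
  posteriors and surface every free choice (priors, variance pooling,
  standardization) as an option.
* The subtype×chemotherapy interaction test at the default study scale
  (pooled adjuvant subset of ~200 patients, mirroring the real pooled
  subset of 180) has modest power; its p-value fluctuates across seeds.
  The calibration and power properties are established at n = 300–400 in
  the tests, where the design supports them.
* Two-reference least squares estimates a single tumor-fraction parameter;
  it is not a multi-cell-type immune deconvolution and reports no
  permutation p-values.
* Survival machinery covers right censoring only — no competing risks, no
  time-varying covariates; proportionality diagnostics are limited to what
  `survival::cox.zph` offers on the returned fit object.
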