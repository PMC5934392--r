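# mpsubtype

Molecular subtyping of gastric cancer expression cohorts into a
**mesenchymal phenotype (MP)** and an **epithelial phenotype (EP)**, with
signature-based classification, survival and treatment-interaction analysis,
stromal-content adjustment, and cross-cohort conserved-gene selection.

## The problem and who this is for

Gastric adenocarcinoma is clinically heterogeneous: patients with apparently
similar stage and histology differ widely in recurrence risk and in benefit
from adjuvant chemotherapy. A recurring explanation is an
epithelial-to-mesenchymal transition (EMT) axis: tumors that have acquired a
mesenchymal expression program carry poor prognosis and respond poorly to
cytotoxic chemotherapy. `mpsubtype` is for computational biologists who want
a tested, reusable implementation of the full discovery-to-validation
workflow for this kind of two-subtype structure in bulk expression cohorts:

1. **Preprocess** — quantile normalization, log2 transform, a
   variation filter (keep genes with ≥ 2-fold deviation from their median in
   ≥ 15 samples), median centering.
2. **Discover** — unsupervised hierarchical clustering (centered Pearson
   distance, average linkage) of tumors plus GIST-like outgroup samples; the
   smaller cluster is the MP (S) cluster.
3. **Derive the signature** — the two-list rule: genes with *P* < 0.001
   (two-sample *t*-test) for MP vs EP **and** for MP vs non-tumor tissue,
   intersected, then restricted to |log2 fold change| ≥ log2(2); weights are
   the MP-vs-EP *t*-statistics.
4. **Classify** — a Bayesian compound covariate predictor (BCCP). Each
   sample gets the scalar
   *c* = Σ<sub>g</sub> *t*<sub>g</sub> · *z*<sub>g</sub>
   (t-statistic-weighted sum of standardized signature-gene expression), and
   class posteriors come from per-class Gaussians of *c*:
   P(MP | c) = π<sub>MP</sub> N(c; μ<sub>MP</sub>, σ) / Σ<sub>k</sub>
   π<sub>k</sub> N(c; μ<sub>k</sub>, σ). Robustness is estimated by honest
   leave-one-out cross-validation (signature re-derived inside every fold)
   and by Cohen's κ against an independent linear SVM.
5. **Survival** — Kaplan–Meier curves, log-rank tests, Cox
   proportional-hazards models with likelihood-ratio inference, and the
   subtype × adjuvant-chemotherapy interaction test (RFS Cox model with
   subtype, chemo, their product, and sex/age/stage) on the stage II–IV,
   no-distant-metastasis subset.
6. **Stromal adjustment** — per-sample tumor fraction by constrained
   least squares against two reference profiles (mean tumor, mean
   surrounding tissue), observed ≈ p·tumor + (1−p)·normal on the linear
   scale; expression adjusted by the published multiplication rule or by
   model-based mixture inversion.
7. **Cross-cohort** — genes significant at *P* < 0.001 with a consistent
   MP−EP direction in *every* cohort; ratio ranking;
   methylation–expression Pearson correlation; hypermutation
   classification (> 11.4 mutations/Mb, strict).

No patient data ship with the package. A first-class synthetic-data
generator (`simulation_config()`, `generate_cohort_set()`) emulates the
multi-cohort structure the analysis assumes — planted signature, batch
shifts, stromal contamination, outgroup samples, proportional-hazards
survival with a subtype×chemotherapy interaction, methylation inversely
coupled to expression, per-subtype log-normal mutation rates — with known
ground truth, so every stage is testable end to end.

## Worked example

```r
library(mpsubtype)

cfg <- simulation_config(n_cohorts = 3, samples_per_cohort = 90,
                         n_genes = 2000, n_signature_genes = 50, seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
mp_pipeline_result
  genes: 2000 input -> 2000 after variation filter; signature 18; conserved 50
  LOOCV: misclassification 0.033 (sens 0.903, spec 1.000)
  C02: accuracy 1.000, log-rank RFS p = 2.72e-07
  C03: accuracy 1.000, log-rank RFS p = 0.000196
  interaction p = 0.00514; chemo HR (EP) 0.46, (MP) 1.32
```

Reading this: the training cohort (C01) yields an 18-gene MP signature; the
BCCP misclassifies 3.3% of training tumors under honest LOOCV; in both
validation cohorts every tumor is assigned its true subtype and the
predicted subtypes split recurrence-free survival sharply (log-rank
p < 3e-4). On the pooled stage II–IV chemotherapy subset, adjuvant
chemotherapy is protective in EP tumors (HR 0.46, 95% CI 0.30–0.72) and not
in MP tumors (HR 1.32, CI 0.74–2.4), and the subtype×chemotherapy
interaction is significant (LRT p = 0.005) — the heterogeneous treatment
effect planted by the generator (`hr_chemo_ep = 0.45`, `hr_chemo_mp = 1`).

Each stage is also callable on its own (`quantile_normalize()`,
`filter_variable_genes()`, `hierarchical_cluster()`, `derive_signature()`,
`train_bccp()`, `loocv_bccp()`, `predict_bccp()`, `cohens_kappa()`,
`km_estimate()`, `logrank_test()`, `cox_fit()`, `interaction_test()`,
`estimate_tumor_fraction()`, `adjust_expression()`, `conserved_genes()`,
`classify_hypermutated()`, …), and the I/O helpers read and write the
tab-delimited expression/clinical/fraction formats plus JSON model
serialization. See the methods vignette (`vignettes/mp-subtyping.Rmd`) for
the modelling details and design choices.

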