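# mcdsl

Causal feature discovery and survival-classification benchmarks for glioma
cohorts.

## The problem

After surgery for diffuse glioma (WHO grade II–IV), clinicians want to know
which of a patient's categorical clinical and molecular characteristics —
age group, Karnofsky performance status, tumor location, WHO grade,
histologic type, extent of resection, adjuvant therapy, IDH / TERT / 1p-19q
marker status and the five-group molecular classification — actually *drive*
3-year progression-free survival (PFS) and overall survival (OS), rather
than merely correlating with them, and how well classifiers built on the
selected factors predict those outcomes.

This package implements that analysis end to end for methodologists who
want to study the behavior of the selection algorithms on fully known
ground truth:

* **`cohort_synth`** — a synthetic cohort generator
  (`generate_cohort()`) emulating a 505-patient surgical series:
  configurable category marginals, deterministic marker consistency
  (IDH = IDH1 ∨ IDH2; codeletion = 1p ∧ 19q;
  `derive_molecular_group()` maps markers to the five-group taxonomy plus
  "Others"; glioblastoma ⇔ grade IV), proportional-hazards survival times
  driven by a *planted causal subset* of features, and administrative
  censoring guaranteeing ≥ 36 months of follow-up.
* **`labels`** — the 3-class label at the 36-month horizon
  (`three_class_label()`: 1 = event-free, 2 = event within 36 months,
  3 = later event) and its binary 3-year outcome (`binarize_3yr()`).
* **`mcdsl`** — the McDSL discovery algorithm: factor combinations
  `S = {x_i, …, x_j}` are collapsed into composite factors
  (`combine()`), ranked by a contingency association measure
  `R(x_s, y)` (Cramér's V by default, `correlation_R()`), and oriented
  with a discrete additive-noise model: `y = f(x_s) + N`, `N ⫫ x_s`.
  The interfered label `ỹ = argmax P(y | x_s)` gives residuals
  `ẽ = y − ỹ`; `x_s → y` is inferred iff `ẽ ⫫ x_s` (Pearson χ², p ≥ α)
  while the reverse fit is rejected (`anm_direction()`). Bootstrap
  stability selection over `B` resamples keeps combinations inferred in
  *every* resample and picks the one with maximal cross-validated
  logistic AUC (`stability_select()`).
* **`selectors`** — the baselines: L1-penalized logistic regression with
  λ chosen by 5-fold CV AUC (`lasso_select()`, via glmnet) and two-stage
  Cox selection (univariate p < 0.10 → multivariate backward elimination
  to p < 0.05; `cox_select()`, via survival), plus bootstrap stability
  profiling (`stability_profile()`).
* **`bench`** — a 354/151-style split (`split_cohort()`), eight
  classifiers (`train_classifier()`: gradient-boosted trees, AdaBoost,
  KNN, logistic regression, naive Bayes, random forest, linear SVM,
  feed-forward neural network), Youden-index thresholds learned on
  training scores (`youden_threshold()`), and six measures — AUC,
  F-score, sensitivity, specificity, PPV, NPV — with 1000-replicate
  percentile-bootstrap 95% CIs (`run_bench()`).

## Worked example

```r
library(mcdsl)

co  <- generate_cohort(cohort_config(n_patients = 505, seed = 1))
lab <- cohort_label(co, "pfs")        # 3-class label + binary 3-year outcome
table(lab$label)
#>   1   2   3
#> 161 297  47

res <- anm_direction(combine(c("who_grade", "mol_group"),
                             co[, glioma_features()]), lab$label)
res
#> ANM direction test (alpha = 0.05)
#>   association p = 3.33e-23
#>   forward residual p = 4.051e-20
#>   backward residual p = 6.357e-33
#>   verdict: none
```

Both directional fits fail here: a proportional-hazards label is *not* an
additive-noise mechanism, and with only two factors the χ² misfit test has
plenty of power (see the vignette on what this implies for recovery).

A planted additive-noise mechanism, by contrast, is oriented correctly:

```r
rep <- simulate_anm_replicate(n = 2000, scale = 2, seed = 3)
anm_direction(rep$composite, rep$y)
#>   association p = 0
#>   forward residual p = 0.8727
#>   backward residual p = 1.846e-132
#>   verdict: forward
```

Stability selection and the benchmark:

```r
run <- stability_select(co[, glioma_features()], lab$label,
                        B = 100, seed = 20260911)
run$selected
#> "location" "histology" "chemotherapy" "mol_group"   (93% of resamples)
range(run$set_sizes)
#> 4 4          # constant size 4: the stability headline vs LASSO (10-15)
                # and Cox (2-8) on the same cohort

report <- run_bench(co, selectors = "lasso", outcomes = "pfs",
                    classifiers = c("lr", "rf"), B_boot = 1000, seed = 1)
```

`report` has one row per selector × classifier × outcome × side with the
six measures and their bootstrap CIs.

There is also a CLI (`inst/cli/mcdsl.R`) with subcommands
`simulate`, `select`, `baselines`, `bench`, `run`.

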