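# mciprog

Predicting conversion from mild cognitive impairment (MCI) to Alzheimer's
disease from baseline T1-weighted MRI and clinical information.

Only about one in five MCI patients progresses to Alzheimer's disease within
two years, and clinical trials need to find them at baseline.  With cohorts
of only a few hundred subjects, end-to-end deep networks overfit; `mciprog`
implements a hybrid alternative:

* a bespoke MRI preprocessing front end — landmark-based 9-DOF similarity
  normalization `min Σᵢ ‖Qᵢ − (S R Pᵢ + T)‖²` refined by masked mutual
  information, cubic B-spline registration to the template, and block-wise
  histogram-range intensity normalization
  `a_k = (u_k^a − l_k^a)/(u_k^w − l_k^w)`, `b_k = −a_k l_k^w + l_k^a`,
  expanded into smooth parameter maps
  `p(X) = Σ_k p_k G(X, X̄_k) / Σ_k G(X, X̄_k)` and back-projected through the
  inverse deformation `p_n(X) = p_w(T_B⁻¹(X))`;
* per-segment 3D DenseNet feature extractors (hippocampus and anterior
  temporal lobe, left/right pooled by mirroring) with a self-attention block
  and an auto-encoder branch, trained under the mixed loss
  `L = (1 − α) L_class + α L_AE`, `α = 0.8`;
* a fusion stage: PCA to one dimension per segment, joined with MMSE, FAQ,
  CDR-SB, ADAS, age and an APOE risk encoding into a 10-vector, quantile
  normalization, and a linear SVM with probability output, ensembled across
  folds at a 0.5 threshold;
* the repeated stratified 10-fold cross-validation-and-test protocol, with
  accuracy / sensitivity / specificity / rank-statistic AUC and ROC curves;
* a synthetic phantom generator (atlas, subjects with known similarity
  transforms, deformations, bias fields, class-dependent hippocampal atrophy
  and cognitive scores) that makes every stage testable by recovery of known
  ground truth, with no external data.

## A worked example

```r
library(mciprog)

atlas  <- make_atlas(64, seed = 1)               # synthetic 64³ template
cohort <- make_cohort(atlas, 30, 30, seed = 20)  # 30 sMCI + 30 pMCI
pre    <- preprocess_cohort(cohort, atlas)       # shape + intensity normalization

train <- c(1:20, 31:50)                          # 20 sMCI + 20 pMCI
test  <- c(21:30, 51:60)                         # 10 + 10 held out
fit <- progression_model(pre$stacks[train], pre$records[train, ],
                         variant = "hybrid",
                         config = tiny_extractor_config(epochs = 5))
print(fit)
#> <progression_model> variant 'hybrid', trained on 40 subjects
#>   fused features: 10 [hippocampus_L, hippocampus_R, ant_temporal_L,
#>   ant_temporal_R, mmse, faq, cdr_sb, adas, age, apoe_risk]; linear SVM (C = 1)

scores <- predict(fit, list(stacks = pre$stacks[test],
                            records = pre$records[test, ]))
compute_metrics(scores, pre$records$label[test])
#> <metric_report> acc 1.000 | AUC 1.000 | sens 1.000 | spec 1.000  (n+ 10, n- 10)
```

(The 20-subject phantom hold-out happens to separate perfectly at these
effect sizes; the 10-seed benchmark on the 200-subject cohort, with
80-subject test sets, gives the more informative mean held-out AUC of about
0.96 for the hybrid model against about 0.77 for the non-image baseline.)

The fitted model prints its 10-feature contract; the metric report gives the
held-out accuracy, rank-statistic AUC, sensitivity (pMCI recall) and
specificity on the 20 phantom subjects never seen in training.  `coef(fit)`
returns the linear SVM weights on the quantile-normalized features,
`plot(fit)` draws an ROC curve, and
`run_phantom_experiment(pre$stacks, pre$records)` reproduces the multi-seed
comparison of the hybrid, non-image-only and end-to-end variants.  A thin
command-line shell (`exec/mciprog`) exposes `simulate`, `preprocess`,
`evaluate` and `predict` over YAML configurations.

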