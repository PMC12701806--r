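# metagcn

Few-shot, imbalance-robust disease classification from functional
connectomes, via graph convolutional networks trained under the
model-agnostic meta-learning (MAML) paradigm.

## The problem

Clinical resting-state fMRI cohorts are small and badly label-imbalanced
(e.g. 30 patients with dementia, 92 with mild cognitive impairment, 243
controls), and each subject is described by a high-dimensional
functional-connectivity matrix plus a few phenotypes (age, sex, APOE4 allele
count). Conventional deep classifiers overfit, collapse onto the majority
class, and — when transductive — must be retrained for every new subject.
`metagcn` is for methodologists and applied neuroimaging groups who want a
tested, fully reproducible reference implementation of the episodic
meta-learning alternative, exercised end to end on synthetic cohorts.

## The model

1. **Feature processing (SE-AE).** Each connectivity matrix is flattened to
   its strict upper triangle, x ∈ R^d with d = n(n−1)/2. A
   squeeze-and-excitation block computes the cohort average z_j = (1/N) Σ_i
   x_ij and a global importance vector s = σ(W₂ δ(W₁ z)) ∈ (0,1)^d
   (δ = ReLU, bottleneck width d/r), rescales every subject x̃ = s ⊙ x, and a
   two-layer-encoder/two-layer-decoder autoencoder compresses x̃ to
   x̂ ∈ R^d̂, d̂ ≪ d. SE and AE are trained jointly and unsupervised by
   reconstruction MSE, selecting the best-validation snapshot.
2. **Task graphs.** Episodic tasks sample k_s support and k_q query subjects
   *per class* (label-balanced by construction). Edges come from phenotype
   similarity: a_ij^u = 1 iff 1 − |s_iu − s_ju|/range_u ≥ β₁, and
   a_ij = 1 iff the mean of the three indicators ≥ β₂ (diagonal zero).
3. **Meta-learned GCN.** On each task graph, with Â = D̃^{−1/2}(A+I)D̃^{−1/2},
   a two-layer GCN X^(l+1) = δ(Â X^(l) θ^(l)) produces node logits. MAML
   learns an initialization θ: the inner update θ′ = θ − α₁∇L_support(θ)
   adapts to a task; the meta-update descends Σ L_query(θ′) (second-order
   gradients via analytic Hessian-vector products; α₁ = 0.01, α₂ = 0.003,
   dropout 0.5). New subjects are predicted by fine-tuning a copy of θ on a
   fresh task's support set — no retraining.

All gradients are hand-derived and verified against finite differences; all
algebra kernels against dense brute-force oracles.

## Worked example

```r
library(metagcn)

coh <- generate_cohort(cohort_config(n_regions = 30, class_counts = c(15, 40, 90),
                                     effect_size = 0.5, seed = 42))
print(coh)
#> fc_cohort: 145 subjects, 30 regions, 435 connectivity features
#> class counts: class1=15, class2=40, class3=90

cfg <- run_config(folds = 3,
                  se_ae = se_ae_config(latent = 32, hidden = 128, epochs = 30),
                  task = task_config(C = 3, M = 60, t = 10),
                  meta = meta_config(iterations = 400),
                  seed = 42)
report <- cross_validate(coh, cfg)
print(report)
#> eval_report: 3 fold-runs
#>   acc: 0.917 +/- 0.021
#>   sen: 0.923 +/- 0.045
#>   spe: 0.960 +/- 0.018
#>   auc: 0.990 +/- 0.009
#>   f1: 0.877 +/- 0.038
#> per-class recall: class1=1.000, class2=0.824, class3=0.944
```

The cohort plants a mean shift of 0.5 correlation units between adjacent
classes on 150 connectivity entries, with demographics partially associated
with class. The report shows stratified 3-fold cross-validation of the whole
pipeline (SE-AE fit, episodic meta-training, per-task fine-tuned
prediction): 91.7% accuracy, and — the point of episodic label balancing —
the 15-subject minority class is recovered perfectly rather than being
absorbed into the 90-subject majority. Sensitivity/specificity/F1 are macro
one-vs-rest averages; AUC is the macro one-vs-rest area under the ROC curve
of the softmax scores.

## Command line

A thin CLI wraps the same functions (config sections map 1:1 onto
`cohort_config()`, `se_ae_config()`, `task_config()`, `meta_config()`,
`run_config()`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "metagcn.R", package = "metagcn"))')
Rscript $CLI simulate --config cfg.yaml --out cohort_dir --seed 1
Rscript $CLI evaluate --config cfg.yaml --cohort cohort_dir --out report.json --seed 1
Rscript $CLI ablate   --config cfg.yaml --cohort cohort_dir --out ablation_dir --seed 1
Rscript $CLI sweep    --config cfg.yaml --cohort cohort_dir --out sweep.tsv --seed 1
```

Reports are timestamp-free JSON: the same config and seed reproduce them
byte for byte.

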