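# wsiSurrogate

Surrogate gene-expression biomarkers from whole-slide images, evaluated
against overall survival.

Tumour gene expression is prognostic but requires sequencing; an H&E
whole-slide image (WSI) exists for almost every patient. `wsiSurrogate`
implements the full surrogate-biomarker workflow for that setting: it
predicts per-sample gene expression from bags of WSI patch features with an
attention-based multiple-instance-learning (AMIL) regressor, and then asks
whether the *predicted* expression carries the same prognostic information
as the measured one. The package is aimed at computational-pathology and
biostatistics practitioners who want the complete, testable analysis chain —
preprocessing, site-aware cross-validation, screening, model training,
concordance evaluation and risk stratification — without GPU-scale
infrastructure.

## The model

A sample is a bag of K patch feature vectors. Each patch is embedded to
`h_k ∈ R^256` (linear + ReLU) and scored by gated-tanh attention

    a_k = softmax_k( wᵀ tanh(V h_k) ),   V ∈ R^{128×256}, w ∈ R^128,

pooled as `h_sum = Σ_k a_k h_k`, and passed through batch normalization,
dropout (p = 0.5) and a linear head — logistic output for expression in
(0, 1) (targets are min–max scaled), identity output for survival risk
scores. Expression models minimize the balanced MSE
`(1/N) Σ w_i (y_i − ŷ_i)²` with inverse-frequency bin weights; survival
models minimize the negative Breslow partial log-likelihood

    L(θ) = −(1/|S|) Σ_{i∈S} [ ĥ(x_i) − log Σ_{j: t_j ≥ t_i} exp(ĥ(x_j)) ].

Around the regressor: Canny-based tile filtering and Macenko stain
normalization; tissue-source-site-preserved, quantile-balanced 5-fold
assignment (exact for ≤ 12 sites); covariate-adjusted Cox screening with a
proportional-hazards filter and BH correction; a cross-validated Pearson
R > 0.4 predictability gate; cross-validated surrogate C-index (Cox fitted
on real expression, evaluated on predicted); best-fold external deployment;
and KMeans-cutoff Kaplan–Meier stratification. A synthetic cohort generator
plants a known image–expression–survival structure so every stage is
testable offline. See the methods vignette
(`vignettes/surrogate-biomarkers.Rmd`) for the full model account.

## Worked example

Simulate a cohort with one prognostic, image-predictable gene (`gene001`,
log-hazard ratio 1 per sd) and one null gene, then run the analysis stages:

```r
library(wsiSurrogate)

cfg <- cohortConfig(nSamples = 120, featureDim = 16, patchesPerBag = 32,
                    seed = 42)
cohort <- simulateCohort(cfg)
cohort
#> SyntheticCohort: 120 samples, 2 genes, 32 patches/bag x 16 features, 10 sites
#> events: 84 / 120

screen <- screenPrognosticGenes(expressionMatrix(cohort), clinicalTable(cohort))
screen[, c("gene", "hr", "ci_low", "ci_high", "adj_p", "ph_p", "prognostic")]
#>      gene        hr    ci_low  ci_high        adj_p      ph_p prognostic
#> 1 gene001 9.2238055 5.1236562 16.60505 2.584271e-13 0.7810236       TRUE
#> 2 gene002 0.7567591 0.5681785  1.00793 5.665270e-02 0.6705755      FALSE
```

The planted gene is flagged (per-sd HR 9.2 on the raw expression scale, well
clear of 1); the null gene is not. Site-preserved folds and the
cross-validated AMIL model:

```r
folds <- cohortFolds(cohort, target = "survival", seed = 42)
cv <- crossvalGeneModels(cohortBags(cohort), expressionMatrix(cohort), folds,
                         pipelineConfig(train = trainConfig(seed = 42)),
                         genes = "gene001")
cv$rTable
#>      gene   r_fold0   r_fold1   r_fold2   r_fold3  r_fold4      cv_r gated
#> 1 gene001 0.9829621 0.9917815 0.9723383 0.9131377 0.979233 0.9678905  TRUE
```

Held-out predictions correlate with the true expression at R ≈ 0.97 in every
fold, so the gene passes the R > 0.4 gate. Its surrogate prognostic value
and a risk-group stratification from the *predicted* expression:

```r
sur <- surrogatePrognosisCV(expressionMatrix(cohort)["gene001", ],
                            cv$perGene$gene001$predictionsInverse,
                            clinicalTable(cohort), folds)
sprintf("surrogate C-index: %.3f +/- %.3f", sur$meanC, sur$sdC)
#> "surrogate C-index: 0.767 +/- 0.052"

stratifyByExpression(cv$perGene$gene001$predictionsInverse,
                     clinicalTable(cohort), gene = "gene001")
#> StratificationResult for gene001 - cutoff 5.9617
#>   high vs low: HR 4.927 [2.920, 8.315] p = 2.33e-09
#>   log-rank p = 3.06e-11  C-index = 0.738
```

Cox models fitted on real expression and deployed on the predicted values
give a mean C-index of 0.77 across folds, and the two-cluster cutoff on
predicted expression separates the cohort into risk groups with an adjusted
hazard ratio of 4.9 — the planted survival signal survives the image
round-trip.

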