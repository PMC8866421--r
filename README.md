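# PanelBurden

Data-driven design of targeted gene panels for estimating exome-wide
mutation-burden biomarkers.

Tumour mutation burden (TMB — the number of non-synonymous somatic
mutations in the exome) and tumour indel burden (TIB — the number of
frameshift indels) help decide which patients are likely to benefit from
immune checkpoint blockade, but whole-exome sequencing is too expensive
for routine use. PanelBurden is for statisticians and genomics groups who
want to (a) choose a targeted gene panel of a prespecified total coding
length, (b) turn the mutation counts observed on that panel into an
accurate estimate of the exome-wide biomarker, and (c) attach a
conservative prediction interval to each estimate. It can also estimate
directly from an existing panel, or augment one with extra genes under a
length budget.

## The model and the estimator

Mutation counts are modelled as independent Poisson variables,

$$M_{igs} \sim \mathrm{Poisson}(\phi_{igs}), \qquad
\log \phi_{igs} = \mu_i + \log \ell_g + \lambda_g + \nu_s + \eta_{gs},$$

for sample *i*, gene *g* (coding length ℓ_g) and variant group *s*
(by default: frameshift indels vs all other non-synonymous mutations).
μ_i is the sample's background mutation rate; the sparse gene effects
λ_g and η_gs are fitted with an L1 penalty whose level κ₁ is chosen by
ten-fold *cell-wise* cross-validation over the (i, g, s) cells.

A biomarker with target groups S̄ (all groups for TMB, indels for TIB) is
estimated by a weighted count sum T(w) = Σ w_gs M₀gs. The weights
minimize the model-based rescaled expected squared error f(w) plus a
length-weighted group-lasso penalty κ₂ Σ ℓ_g‖w_g‖₂, so whole genes drop
out and the surviving genes form the panel; κ₂ is mapped to a length
budget by a grid walk, the weights are refitted unpenalized on the
selected support (closed form), and Markov's inequality on the plug-in
mean squared error gives level-(1−α) prediction intervals. Count-scaling
and ordinary-least-squares baselines, R², precision–recall and ROC
metrics are included, along with a generative simulator so the whole
pipeline is testable without any external data. See the vignette
(`vignettes/panel-design-methods.Rmd`) for the full methodology.

## Worked example

Simulate a cohort from the generative model, fit it, select a panel using
10% of the exome length, and predict TMB for fresh samples:

```r
library(PanelBurden)

# a 200-sample, 500-gene cohort with sparse gene effects
model <- sampleParams(syntheticConfig(nSamples = 200, nGenes = 500, seed = 1))
train <- sampleCounts(model@params, model@geneLengths, seed = 2)
train
#> MutationExperiment: 500 genes x 200 samples, groups {other, indel}, 50168 mutations
summary(as.numeric(biomarkerValues(train, tmbSpec())))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    7.00   78.75  141.50  250.84  305.50 2087.00

# penalized Poisson fit, penalty chosen by cell-wise cross-validation
fit <- fitGenerativeModel(train, config = fitConfig(gridLength = 12,
                                                    nFolds = 10, seed = 3))
fit
#> GenerativeFit: 200 samples, 500 genes, groups {other, indel}; kappa1 = 5.324; sparsity lambda 43.8%, eta 96.8%

# panel selection at a 10%-of-exome budget, then refit on the support
budget <- 0.1 * sum(model@geneLengths)
est <- buildEstimator(fit, train, model@geneLengths, tmbSpec(),
                      budget = budget)
est
#> BiomarkerEstimator for TMB: panel of 45 genes (0.06 Mb), K = 2087

# predictions and 90% prediction intervals for fresh samples
fresh <- sampleCohort(model, nSamples = 200, seed = 4)
pred <- predict(est, fresh$counts)
truth <- biomarkerValues(fresh$counts, tmbSpec())
head(predictionInterval(est, pred, alpha = 0.1), 3)
#>   sample  estimate     lower    upper alpha
#> 1  t0001 197.02368  80.73476 313.3126   0.1
#> 2  t0002  94.57137  14.01058 175.1322   0.1
#> 3  t0003 362.52357 204.76094 520.2862   0.1

evaluatePredictions(truth, pred, threshold = 300)
#>          r2     auprc     auroc   n prevalence
#> 1 0.9674238 0.9779229 0.9919068 200      0.255
```

Reading: the cross-validated fit zeroes 43.8% of the per-gene effects;
the selected 45-gene panel uses under a tenth of the simulated exome yet
predicts TMB on fresh samples with R² = 0.97 and classifies high-TMB
(≥ 300 mutations) samples with AUPRC 0.98 against a 25.5% prevalence.
The naive count estimator on the same panel reaches only R² = 0.24 here,
because the selected genes are preferentially highly mutated and plain
length rescaling over-extrapolates their burden.

Real data enter through `readMAF()` + `aggregateCounts()` (MAF-style TSV
plus a `gene`/`length_bases` table); `splitSamples()` makes seeded
train/validation/test partitions. The same pipeline is scriptable from a
shell via the installed `exec/panelburden` tool
(`simulate`, `fit`, `select-panel`, `augment`, `predict`, `evaluate`).

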