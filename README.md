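# jkomics

Multi-omics cancer subtype classification with jumping-knowledge graph
networks, in R.

Tumour cohorts are routinely profiled on several molecular layers — copy-number
alteration (CNA), DNA methylation (MET), mRNA expression and reverse-phase
protein arrays (RPPA). Each layer sees a different facet of the same
patients, and molecular subtypes (and their prognosis) are easier to
resolve when the layers are integrated. `jkomics` is aimed at
computational-biology groups who want a transparent, dependency-light
implementation of graph-based multi-omics integration that runs on a
laptop-scale cohort (hundreds of patients) and is testable end to end
against synthetic cohorts with known structure.

## The model

For each omics layer *m*, patients are connected by a Gaussian-kernel
affinity with a locally adaptive bandwidth,

```
s_ij = exp( -d_ij / (2 mu eps_ij) ),   eps_ij = (dbar_i(k) + dbar_j(k) + d_ij) / 3
```

on squared-Euclidean distances (`mu = 0.5`, `k = 20`), sparsified to each
patient's top-k neighbours. Similarity network fusion (SNF) cross-diffuses
the per-layer graphs,

```
P(v) <- S(v) %*% mean of P(u), u != v %*% t(S(v))
```

for 20 iterations, into one consensus patient network. A multimodal
autoencoder (one encoder/decoder per layer around a shared latent, loss
`sum_m w_m * MSE_m` with `w = (0.2, 0.2, 0.3, 0.3)`) learns a patient-level
representation. Jumping-knowledge graph branches — GCN steps
`h(l) = ReLU(Ahat h(l-1) W(l))` with layers 0..L concatenated — are trained
per omics layer (raw features + that layer's graph) and for the patient
pathway (autoencoder latent + fused graph). The five branch embeddings are
concatenated and classified by a two-head graph attention layer over the
consensus network's top-k neighbourhoods. Classification is scored with
cross-validated macro precision/recall/F1; the final embedding is mapped to
a risk score by a ridge Cox head and evaluated with Kaplan-Meier curves,
the log-rank test and the concordance index.

All neural components are dense base-R implementations with manual
backpropagation and Adam; the only model dependencies are `survival`,
`glmnet` and `jsonlite`.

## Worked example

```r
library(jkomics)

spec <- synth_spec(n_samples = 120, class_proportions = c(0.5, 0.3, 0.2),
                   feature_dims = c(300, 300, 300, 40),
                   informative_frac = 0.1, effect_size = c(0.6, 0.8, 1, 0.5),
                   noise_sd = 1, missing_rate = 0.02,
                   hazard_ratios = c(5, 2, 1), censor_rate = 0.3, seed = 42)
cohort <- generate_cohort(spec)
cohort
#> <multiomics_dataset> 120 samples, 3 classes (60/36/24)
#>   modalities: CNA[300] MET[300] mRNA[300] RPPA[40]
#>   survival: 89 events / 120 samples

fit <- jkomics(cohort, train_config(n_folds = 3, seed = 1))
fit
#> <jkomics> 120 samples, 3 classes, cv over 3 folds
#> <metrics_report> 3 folds, 3 classes (macro, %)
#>   precision  96.68 +/- 0.66
#>   recall     97.96 +/- 0.64
#>   f1         97.20 +/- 0.61
#>   survival: log-rank chi2 = 30.90 (p = 2.71e-08), C-index = 0.671
```

The macro metrics are unweighted class means over the three held-out folds
(mean ± sd, %): the planted subtype structure is recovered almost
perfectly. The survival line says that a median split of the learned risk
scores separates the two groups' survival curves decisively (log-rank
chi-square 30.9, p ≈ 3e-8) and that the prevalidated risk scores order
patient survival correctly for 67% of comparable patient pairs — as expected, since class 1
was generated with five times the baseline hazard.

`predict(fit)` returns the per-fold test predictions with class
probabilities, `plot(fit)` shows the embedding in principal-component
space, `run_ablation()` reproduces the leave-one-omics-out, single-branch
and JK-vs-GCN comparisons, and `write_results(fit, dir)` exports metrics,
predictions, embeddings and survival curves as delimited text. Real
cohorts enter through `read_omics_table()` / `align_samples()` or a
`read_dataset_bundle()` directory; a thin command-line wrapper is installed
at `inst/cli/jkomics`.

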