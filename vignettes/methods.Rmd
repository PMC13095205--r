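---
title: "Multi-omics subtype classification with jumping-knowledge graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics subtype classification with jumping-knowledge graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models implemented in `jkomics`, the choices
behind their parameters, what the synthetic cohorts emulate, and the known
limitations. No numbers are quoted here that the package's tests and
acceptance script do not themselves compute.

## The problem

Cancer cohorts profiled on several molecular layers — copy-number
alterations (CNA), DNA methylation (MET), mRNA expression and reverse-phase
protein arrays (RPPA) — carry complementary subtype information. The
package classifies patients into molecular subtypes by integrating these
layers through patient-similarity graphs and graph neural networks, and
evaluates whether the learned patient embedding also stratifies overall
survival.

## Preprocessing

Input tables follow the cBioPortal export dialect. Cleaning proceeds in a
fixed order per modality:

1. drop features whose missing fraction strictly exceeds 10% (a feature at
   exactly 10% is retained);
2. impute the remaining missing cells with zero;
3. drop features whose post-imputation zero fraction strictly exceeds 10%
   (such features carry little variability).

Sample barcodes are truncated to their first 12 characters (patient-level
ids), duplicates are removed keeping the last occurrence, and samples are
kept only when they are present in every modality and carry a subtype
label; survivors are sorted lexicographically so every container shares one
sample order. The operation is idempotent, and every drop is recorded in a
provenance attribute.

Feature scaling is not part of the source procedure but is required by
Gaussian-kernel distances and gradient training, so features are z-scored:
on cohort statistics for graph construction (graphs are built once,
transductively), and on training-fold statistics only for everything that
feeds a model, so no test-fold statistic reaches training.

## Patient graphs and their fusion

Per modality, squared-Euclidean distances between patients are converted to
similarities with a locally-scaled Gaussian kernel

$$s_{ij} = \exp\!\left(-\frac{d_{ij}}{2\,\mu\,\varepsilon_{ij}}\right),
\qquad
\varepsilon_{ij} = \tfrac{1}{3}\bigl(\bar d_i^{(k)} + \bar d_j^{(k)} + d_{ij}\bigr),$$

where $\bar d_i^{(k)}$ is the mean distance from patient $i$ to its $k$
nearest neighbours. The scale parameter of the Gaussian kernel is thus
resolved locally per pair, governed by $\mu$ (default 0.5) and $k$
(default 20) — the similarity-network-fusion lineage of this kernel. A
single global bandwidth per modality is the alternative reading; the local
form is used because it is the only one the $(\mu, k)$ parameterisation
identifies. Each affinity matrix is sparsified to its top-$k$ neighbours
per row (ties broken by lower sample index) and symmetrised by elementwise
maximum; disconnected results are flagged with a component count but still
usable downstream.

Similarity network fusion (SNF) merges the per-omics graphs by
cross-diffusion. Each view $v$ keeps a row-stochastic status kernel
$P^{(v)}$ (off-diagonal mass $\tfrac12$, diagonal $\tfrac12$) and a local
kernel $S^{(v)}$ normalised over the $k$ strongest neighbours; the update

$$P^{(v)} \leftarrow S^{(v)}\,\overline{P^{(-v)}}\,S^{(v)\top}$$

is followed by re-symmetrisation and re-normalisation. The iteration count
is fixed at 20 with a reported max-absolute-change diagnostic rather than an
early-stopping rule, since the source procedure prescribes a predefined
number of iterations; with identical views the recursion reaches its fixed
point well below $10^{-6}$ by iteration 20 (asserted in tests). The fused
network is the view average of the converged status kernels, symmetrised.

## The model

**Multimodal autoencoder.** One encoder per modality
($p_m \to \min(p_m, 500)$, ReLU), encoder outputs concatenated and
projected linearly to a shared latent of width 100 (matching the graph
branches' hidden width), and one decoder per modality (latent
$\to \min(p_m,500) \to p_m$). The loss is a weighted sum of per-modality
mean squared errors with weights $(\alpha,\beta,\gamma,\delta) =
(0.2, 0.2, 0.3, 0.3)$ for (CNA, MET, mRNA, RPPA), constrained to sum to 1;
mean squared error instantiates the generic reconstruction loss because the
inputs are continuous. Training is full-batch Adam (learning rate 0.001,
150 epochs — mirroring the branch settings, as autoencoder-specific values
are not separately identified). The autoencoder is trained as a separate
unsupervised stage on training-fold rows and then encodes every patient.

**Jumping-knowledge branches.** Two input pathways produce latent
representations: per modality, the raw (standardised) features with that
modality's affinity graph; and a patient-level branch feeding the
autoencoder latent through the fused network. Each branch stacks $L$
graph-convolution steps

$$h^{(l)} = \mathrm{ReLU}\bigl(\hat A\, h^{(l-1)} W^{(l)}\bigr),
\qquad \hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2},$$

on the weighted adjacency (the neighbourhood aggregation is instantiated as
the GCN symmetric-normalised mean with self-loops, which makes the ablation
against a plain GCN isolate exactly the jumping-knowledge mechanism), and
aggregates layers 0..$L$ by concatenation (default; elementwise max is
available). $h^{(0)}$ is a linear projection of the input to the hidden
width — raw dimensionalities in the thousands would otherwise dwarf the
hidden layers in the concatenation. Branch depths default to 2; the
`coadread` profile (a many-subtype colorectal-like cohort) deepens them to
3 (per-omics) and 4 (patient). Each branch carries an auxiliary linear
softmax head trained with cross-entropy on training nodes only
(transductive, full-graph forward, masked loss) — per-branch supervision is
implied by the per-branch performance the ablation harness reports — and
the pre-head aggregated representation is the branch embedding. Hidden
width 100, dropout 0.5 on hidden layers, Adam at 0.001 for a fixed 150
epochs without early stopping.

**Attention classifier.** The five branch embeddings are concatenated and
classified by one graph attention layer (2 heads of width 100,
concatenated, ELU) followed by a linear softmax head. Attention logits
$e_{ij} = \mathrm{LeakyReLU}_{0.2}(a^\top[W h_i \,\|\, W h_j])$ are
softmax-normalised over each node's self-inclusive neighbourhood. The
"alpha = 0.2" setting is read as the LeakyReLU negative slope, its
conventional meaning in graph attention. Class imbalance is left to plain
unweighted cross-entropy, since only macro-averaged metrics are reported
downstream.

The fused SNF matrix is dense, so "neighbourhood" would degenerate to the
whole cohort for the attention layer. The classifier therefore runs on the
top-$k$ sparsification of the consensus network (the same $k$-nearest-
neighbour rule every affinity graph uses), while the patient branch keeps
the dense weighted consensus — its GCN aggregation uses the edge weights,
which the attention mask cannot. This choice was made after observing that
whole-cohort attention sometimes failed to sharpen during training and
collapsed a class; with an actual neighbourhood structure the classifier
trains to near-zero loss reliably.

## Evaluation protocol

The default protocol is stratified 5-fold cross-validation: graphs are
built once per cohort; per fold, standardisation, autoencoder, branches and
classifier are fit on the training fold and the held-out fold is predicted.
A single stratified 75/25 holdout is available behind `eval_mode =
"holdout"`, as both protocols appear in the source experiments; the
cross-validated numbers are the reported ones. Metrics are macro-averaged
precision, recall and F1 (unweighted class means; a class never predicted
contributes precision 0), reported as mean and standard deviation over
folds.

For survival, a final all-training fit produces the cohort embedding; a
ridge-penalised Cox head (glmnet) maps it to a risk score; the penalty is
chosen by deterministic cross-validation and the reported scores are
prevalidated — each patient's linear predictor comes from a model fitted
without that patient's fold, so the log-rank test and concordance index are
not inflated by in-sample optimism (with a permuted-survival null the
concordance stays at one half, asserted in tests) — the source procedure does not
define how embeddings become risk scores, and a proportional-hazards linear
head is the simplest model-derived scalar consistent with median-split and
concordance usage; a precomputed score (e.g. a class probability) can be
supplied instead. Patients are split at the median score (ties to the
low-risk group), compared by Kaplan-Meier curves and the two-group log-rank
test, and ranked by the concordance index (comparable pair: $t_i < t_j$
with an event at $i$; risk ties count one half).

## Synthetic cohorts

`generate_cohort()` emulates the structure of the real cohorts: four
modalities of differing dimensionality (three high-dimensional, one
low-dimensional protein-like layer), imbalanced subtypes, subtype-specific
mean shifts in a feature subset per modality with modality-specific
strengths, Gaussian noise, injected missingness, and exponential survival
with class-dependent hazards plus independent censoring calibrated to a
target rate. Class mean patterns are random sign vectors over the
informative features, separating every class pair in expectation. The
reference recipe fixes the study conditions used by the acceptance checks:
200 patients, three classes (50/30/20%), dimensions 500/500/500/60,
10% informative features, effect sizes (0.6, 0.8, 1.0, 0.5) — the
protein-like layer deliberately weakest — unit noise, 2% missingness,
hazard ratios (5, 2, 1), 30% censoring, seed 17. These sizes keep a full
5-fold run to a few minutes on one CPU while leaving all model
hyperparameters at their real-data defaults.

What the generator does not emulate: methylation beta-value marginals,
copy-number segment structure, feature-feature correlation, batch effects.
Passing the acceptance checks therefore demonstrates that the pipeline
recovers planted mean-shift structure and survival orderings under
realistic shapes and noise — not that it attains any particular accuracy
on real tumours.

`generate_twohop_graph()` builds a node-classification probe whose class
signal is only resolvable at the two-hop graph scale: labelled subjects
with noise features connect to relays (noise) that connect to class-marked
beacons, and beacons of all classes form a dense clique that mixes deeper
propagation.

## The jumping-knowledge ablation: a negative finding

The ablation harness compares each branch's concatenation aggregation
against a final-layer-only GCN of equal depth. On the two-hop probe — run
at depth 4 with training pushed to convergence (learning rate 0.01, 300
epochs, dropout 0.3) so that neither model is handicapped by
under-training — the expected advantage of layer concatenation does not
materialise: across many probe variants (node degrees, shared relay pools,
silent subject features, misleading one-hop plus correct two-hop signal,
noise and effect scans), the plain GCN matches or slightly beats the
jumping-knowledge branch unless both saturate. Two mechanisms explain
this. First, the self-loop in $\hat A$ acts as an implicit residual
connection: the two-hop signal reaches the final layer diluted but with its
signal-to-noise ratio intact, so a converged deep GCN still recovers it.
Second, with only tens of labelled nodes, the GCN's narrower final
representation is statistically favoured over the $(L{+}1)\times$-wide
concatenation, which must learn to ignore its noisy shallow slices. The
corresponding acceptance check is left failing rather than re-tuned, and
the source experiments themselves report the plain GCN ahead on two of
seven cohorts — the advantage of jumping knowledge appears to be
dataset-dependent rather than universal.

## Numerical choices and degenerate inputs

* All randomness flows from one global seed through per-stage seeds derived
  by hashing the stage name, so any stage can be reproduced in isolation
  and two runs with the same seed are byte-identical.
* Glorot-uniform initialisation; Adam with the standard moment settings;
  full-batch gradients (cohorts are hundreds of patients).
* Kernel bandwidths are floored at $10^{-12}$ so all-identical points do
  not divide by zero; isolated graph nodes are epsilon-regularised with a
  warning during SNF normalisation.
* Top-$k$ ties break by lower sample index; elementwise-max aggregation
  routes gradients to the first maximising layer; median ties in the risk
  split go to the low-risk group.
* Constant features standardise to zero; constant risk scores are an error
  advising inspection rather than a silent half-split.
* Non-finite losses abort with the epoch index.

## Limitations

* The neural stages are dense base-R implementations intended for cohorts
  of up to a few thousand patients; no sparse message passing or GPU path.
* Graphs are built once per cohort (transductive); a per-fold rebuild is a
  caller-side loop rather than a flag.
* The survival head assumes proportional hazards and is fitted after
  classification training, not jointly.
* Identifier harmonisation across gene annotation versions, batch
  correction, and downloading public cohorts are out of scope; readers of
  the bundled format are expected to have resolved those upstream.
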