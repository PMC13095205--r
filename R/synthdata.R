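# Synthetic multi-omics cohorts with known subtype structure: per-modality
# mean-shift signal in a subset of features, Gaussian noise, injected
# missingness, and subtype-dependent exponential survival with independent
# censoring. Used throughout the tests so the whole pipeline is exercised
# without any download.

#' Specification of a synthetic multi-omics cohort
#'
#' @param n_samples Cohort size.
#' @param class_proportions Simplex vector of subtype proportions.
#' @param feature_dims Integer vector of per-modality feature counts
#'   (conventionally three high-dimensional layers and one low-dimensional
#'   protein-array-like layer).
#' @param informative_frac Per-modality fraction of informative features,
#'   in `[0, 1]` (recycled).
#' @param effect_size Per-modality mean shift of informative features in
#'   noise-sd units (recycled).
#' @param noise_sd Gaussian noise standard deviation.
#' @param missing_rate Fraction of cells set missing before preprocessing,
#'   in `[0, 1)`.
#' @param hazard_ratios Per-class hazard multipliers (positive).
#' @param censor_rate Target fraction of censored patients, in `[0, 1)`.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_samples, class_proportions, feature_dims,
                       informative_frac = 0.1, effect_size = 1,
                       noise_sd = 1, missing_rate = 0,
                       hazard_ratios = NULL, censor_rate = 0.3, seed = 1) {
  stopifnot(n_samples >= length(class_proportions),
            abs(sum(class_proportions) - 1) < 1e-8,
            all(feature_dims >= 1),
            all(informative_frac >= 0 & informative_frac <= 1),
            all(effect_size >= 0), noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            censor_rate >= 0, censor_rate < 1)
  k <- length(class_proportions)
  if (is.null(hazard_ratios)) hazard_ratios <- rep(1, k)
  stopifnot(length(hazard_ratios) == k, all(hazard_ratios > 0))
  m <- length(feature_dims)
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = class_proportions,
                 feature_dims = as.integer(feature_dims),
                 informative_frac = rep_len(informative_frac, m),
                 effect_size = rep_len(effect_size, m),
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 hazard_ratios = hazard_ratios,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

# deterministic largest-remainder allocation of n samples to proportions
allocate_classes <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(-(raw - counts), seq_along(props))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic multi-omics cohort
#'
#' Per modality, a subset of features is informative: class `k` shifts them
#' by `effect_size * s_k` where `s_k` is a class-specific random sign
#' pattern (distinct patterns separate every class pair in expectation);
#' remaining features have mean 0. Gaussian noise is added everywhere,
#' missing cells are injected at `missing_rate`, and survival times are
#' exponential with class-dependent hazard plus independent exponential
#' censoring calibrated to the target censor rate. Fully deterministic
#' given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [multiomics_dataset()] with labels `C1..Ck` and survival data;
#'   matrices contain `NA` at injected-missing cells (run
#'   [filter_and_impute()] before modelling).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(stage_seed(spec$seed, "cohort"))
  n <- spec$n_samples
  k <- length(spec$class_proportions)
  counts <- allocate_classes(n, spec$class_proportions)
  labels <- factor(rep(paste0("C", seq_len(k)), counts),
                   levels = paste0("C", seq_len(k)))
  ids <- sprintf("SYN-%08d", seq_len(n))
  mods <- omics_modalities()[seq_along(spec$feature_dims)]
  omics <- list()
  for (m in seq_along(spec$feature_dims)) {
    p <- spec$feature_dims[m]
    n_inf <- round(spec$informative_frac[m] * p)
    mu <- matrix(0, k, p)
    if (n_inf > 0) {
      inf_idx <- seq_len(n_inf)   # leading block; location carries no signal
      signs <- matrix(sample(c(-1, 1), k * n_inf, replace = TRUE), k, n_inf)
      mu[, inf_idx] <- spec$effect_size[m] * signs
    }
    x <- mu[as.integer(labels), , drop = FALSE] +
      matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
    if (spec$missing_rate > 0) {
      miss <- matrix(runif(n * p) < spec$missing_rate, n, p)
      x[miss] <- NA_real_
    }
    dimnames(x) <- list(ids, sprintf("%s_f%04d", mods[m], seq_len(p)))
    omics[[mods[m]]] <- omics_matrix(x, mods[m])
  }
  base_rate <- 0.01   # hazard 1 ~ 69-month median survival
  rates <- base_rate * spec$hazard_ratios[as.integer(labels)]
  event_time <- rexp(n, rates)
  if (spec$censor_rate > 0) {
    # censoring rate solving mean_k P(censor first) = target
    target <- spec$censor_rate
    fr <- function(r) mean(r / (r + base_rate * spec$hazard_ratios[as.integer(labels)])) - target
    r <- stats::uniroot(fr, c(1e-9, 1e3))$root
    cens_time <- rexp(n, r)
  } else {
    cens_time <- rep(Inf, n)
  }
  time <- pmin(event_time, cens_time)
  event <- as.numeric(event_time <= cens_time)
  survival <- data.frame(time = time, event = event)
  multiomics_dataset(omics, labels, survival)
}

#' Canonical synthetic cohort recipe
#'
#' The repository's reference study conditions: 200 patients, 3 imbalanced
#' subtypes (50/30/20%), three high-dimensional modalities (500 features)
#' plus one low-dimensional protein-array-like modality (60 features),
#' 10% informative features per modality with modality-specific effect
#' sizes (0.6, 0.8, 1.0, 0.5; the protein layer intentionally weakest),
#' unit noise, 2% injected missingness, class hazard ratios 5/2/1 and 30%
#' censoring, seed 17.
#'
#' @return A [synth_spec()].
#' @export
reference_recipe <- function() {
  synth_spec(n_samples = 200,
             class_proportions = c(0.5, 0.3, 0.2),
             feature_dims = c(500, 500, 500, 60),
             informative_frac = 0.1,
             effect_size = c(0.6, 0.8, 1.0, 0.5),
             noise_sd = 1,
             missing_rate = 0.02,
             hazard_ratios = c(5, 2, 1),
             censor_rate = 0.3,
             seed = 17)
}

#' Synthetic node-classification problem with two-hop class signal
#'
#' Builds a graph whose class information is only resolvable at the two-hop
#' scale: labelled "subject" nodes have pure-noise features and connect to
#' noise-feature "relay" nodes of their class; relays connect to "beacon"
#' nodes whose features encode the class; beacons of all classes are densely
#' interconnected. A subject's own and one-hop features are uninformative,
#' its two-hop neighbourhood is informative, and deeper propagation mixes
#' classes through the beacon clique - the regime where aggregating
#' intermediate layers (jumping knowledge) should beat a same-depth plain
#' GCN that only uses its final layer.
#'
#' @param n_subjects Labelled subject nodes per class (default 30).
#' @param n_classes Number of classes (default 3).
#' @param n_relays Relay nodes per subject (default 2).
#' @param n_beacons Beacon nodes per class (default 10).
#' @param feature_dim Feature dimension (default 16).
#' @param noise_sd Noise standard deviation (default 1).
#' @param beacon_strength Beacon signal magnitude (default 3).
#' @param seed Integer seed.
#' @return List with `features`, `graph` (an [affinity_graph()]), `labels`
#'   (factor over all nodes) and `subject_mask` (logical; only subjects are
#'   classified).
#' @export
generate_twohop_graph <- function(n_subjects = 30, n_classes = 3,
                                  n_relays = 2, n_beacons = 10,
                                  feature_dim = 16, noise_sd = 1,
                                  beacon_strength = 3, seed = 1) {
  set.seed(stage_seed(seed, "twohop"))
  n_subj <- n_subjects * n_classes
  n_rel <- n_subj * n_relays
  n_bea <- n_beacons * n_classes
  n <- n_subj + n_rel + n_bea
  cls_subj <- rep(seq_len(n_classes), each = n_subjects)
  cls_bea <- rep(seq_len(n_classes), each = n_beacons)
  # class signature directions for beacon features
  sig <- matrix(rnorm(n_classes * feature_dim), n_classes)
  sig <- sig / sqrt(rowSums(sig^2))
  X <- matrix(rnorm(n * feature_dim, sd = noise_sd), n, feature_dim)
  bea_rows <- n_subj + n_rel + seq_len(n_bea)
  X[bea_rows, ] <- X[bea_rows, ] + beacon_strength * sig[cls_bea, ]
  A <- matrix(0, n, n)
  rel_of <- function(s) n_subj + (s - 1) * n_relays + seq_len(n_relays)
  for (s in seq_len(n_subj)) {
    A[s, rel_of(s)] <- 1
    # each relay links to a few beacons of the subject's class
    for (r in rel_of(s)) {
      b <- bea_rows[cls_bea == cls_subj[s]]
      A[r, sample(b, min(3, length(b)))] <- 1
    }
  }
  A[bea_rows, bea_rows] <- 1    # dense cross-class beacon clique
  A <- pmax(A, t(A))
  diag(A) <- 0
  ids <- sprintf("N%04d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  labels <- factor(c(cls_subj,
                     rep(cls_subj, each = n_relays),
                     cls_bea),
                   levels = seq_len(n_classes))
  rownames(X) <- ids
  list(features = X,
       graph = affinity_graph(A, k = n_relays, modality = "twohop"),
       labels = labels,
       subject_mask = seq_len(n) <= n_subj)
}
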