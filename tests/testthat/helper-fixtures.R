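# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops over the defining formulas, never
# reusing package internals, so they stay independent of the code they check.

# small labelled matrix with sample/feature ids
toy_matrix <- function(n, p, prefix = "S", seed = NULL, modality = "CNA") {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  omics_matrix(v, modality)
}

# a small cohort whose classes separate well; cheap to train on
small_cohort <- function(n = 60, seed = 7, missing_rate = 0.02) {
  generate_cohort(synth_spec(
    n_samples = n, class_proportions = c(0.4, 0.35, 0.25),
    feature_dims = c(40, 40, 40, 15), informative_frac = 0.3,
    effect_size = c(1, 1, 1.2, 0.8), noise_sd = 1,
    missing_rate = missing_rate, hazard_ratios = c(4, 2, 1),
    censor_rate = 0.3, seed = seed))
}

# reduced-size pipeline settings for unit tests (defaults stay untouched in
# acceptance runs)
small_config <- function(seed = 3, ...) {
  train_config(knn_k = 8, n_folds = 3, ae_epochs = 40, jk_epochs = 60,
               gat_epochs = 60, ae_hidden_cap = 64, ae_latent_dim = 16,
               jk_hidden = 16, gat_hidden = 16, seed = seed, ...)
}

## ---- oracles -------------------------------------------------------------

# squared-euclidean distances by double loop
oracle_sqeuclidean <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum((x[i, ] - x[j, ])^2)
  d
}

# locally-scaled Gaussian kernel, straight-line transcription
oracle_affinity <- function(d, mu, k) {
  n <- nrow(d)
  mk <- numeric(n)
  for (i in seq_len(n)) {
    others <- sort(d[i, -i])
    mk[i] <- mean(others[seq_len(k)])
  }
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    eps <- (mk[i] + mk[j] + d[i, j]) / 3
    s[i, j] <- exp(-d[i, j] / (2 * mu * max(eps, 1e-12)))
  }
  diag(s) <- 1
  s
}

# top-k sparsification by explicit ranking + union with transpose
oracle_knn_edges <- function(s, k) {
  n <- nrow(s)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(-s[i, -i])
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    keep[i, nb] <- TRUE
  }
  keep | t(keep)
}

# SNF normalisations and update, loop transcription
oracle_status_kernel <- function(w) {
  n <- nrow(w)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(w[i, -i])
    for (j in seq_len(n)[-i]) p[i, j] <- w[i, j] / (2 * s)
    p[i, i] <- 0.5
  }
  p
}

oracle_local_kernel <- function(w, k) {
  n <- nrow(w)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    nb <- others[order(-w[i, others])][seq_len(k)]
    s[i, nb] <- w[i, nb] / sum(w[i, nb])
  }
  s
}

oracle_snf <- function(w_list, k, t_max) {
  m <- length(w_list)
  P <- lapply(w_list, oracle_status_kernel)
  S <- lapply(w_list, oracle_local_kernel, k = k)
  n <- nrow(w_list[[1]])
  for (t in seq_len(t_max)) {
    newP <- vector("list", m)
    for (v in seq_len(m)) {
      pm <- matrix(0, n, n)
      for (u in seq_len(m)[-v]) pm <- pm + P[[u]]
      pm <- pm / (m - 1)
      p <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n))
        p[i, j] <- sum(outer(S[[v]][i, ], S[[v]][j, ]) * pm)
      p <- (p + t(p)) / 2
      newP[[v]] <- oracle_status_kernel(p)
    }
    P <- newP
  }
  fused <- Reduce(`+`, P) / m
  (fused + t(fused)) / 2
}

# product-limit estimate over distinct times, explicit risk-set tracking
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# two-group log-rank chi-square by event-time enumeration
oracle_logrank <- function(time, event, group1) {
  ts <- sort(unique(time[event == 1]))
  O1 <- sum(event == 1 & group1)
  E1 <- 0
  V1 <- 0
  for (t in ts) {
    n_at <- sum(time >= t)
    n1 <- sum(time >= t & group1)
    d <- sum(time == t & event == 1)
    E1 <- E1 + d * n1 / n_at
    if (n_at > 1)
      V1 <- V1 + n1 * (n_at - n1) * d * (n_at - d) / (n_at^2 * (n_at - 1))
  }
  (O1 - E1)^2 / V1
}

# concordance by exhaustive pair loop
oracle_cindex <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# macro metrics from an explicit confusion-matrix loop
oracle_macro <- function(true, pred, classes) {
  prec <- rec <- f1 <- numeric(length(classes))
  for (c in seq_along(classes)) {
    tp <- sum(true == classes[c] & pred == classes[c])
    fp <- sum(true != classes[c] & pred == classes[c])
    fn <- sum(true == classes[c] & pred != classes[c])
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  c(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# mean silhouette width from a distance matrix, by loops
oracle_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
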