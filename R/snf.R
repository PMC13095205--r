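# Similarity network fusion: cross-diffusion of per-omics affinity graphs
# into one consensus patient network.

#' Normalise affinity graphs into SNF status and local kernels
#'
#' For each view `v` builds the full status kernel `P^(v)` with the
#' mass-preserving normalisation `p_ij = w_ij / (2 * sum_{l != i} w_il)` off
#' the diagonal and `p_ii = 1/2` (every row sums to 1), and the local kernel
#' `S^(v)` that row-normalises the `k` strongest neighbours of each node and
#' is zero elsewhere. Isolated nodes (zero off-diagonal row) are
#' epsilon-regularised with a warning.
#'
#' @param graphs List of at least two [affinity_graph()] objects sharing
#'   identical sample ids and order.
#' @param k Neighbour count for the local kernels; defaults to the first
#'   graph's `k`.
#' @return An object of class `"snf_state"`: list with `P` (status kernels),
#'   `S` (local kernels), `sample_ids`, `k`, `iteration`.
#' @export
normalize_kernels <- function(graphs, k = NULL) {
  stopifnot(length(graphs) >= 2)
  ids <- sample_ids(graphs[[1]])
  for (g in graphs)
    if (!identical(sample_ids(g), ids))
      stop("all graphs must share identical sample ids and order")
  if (is.null(k)) k <- graphs[[1]]$k
  n <- length(ids)
  P <- lapply(graphs, function(g) status_kernel(g$weights))
  S <- lapply(graphs, function(g) local_kernel(g$weights, k))
  structure(list(P = P, S = S, sample_ids = ids, k = as.integer(k),
                 iteration = 0L),
            class = "snf_state")
}

status_kernel <- function(w) {
  off <- w
  diag(off) <- 0
  rs <- rowSums(off)
  if (any(rs == 0)) {
    warning("isolated node(s) in affinity graph; epsilon-regularizing")
    off[rs == 0, ] <- 1e-12
    diag(off) <- 0
    rs <- rowSums(off)
  }
  p <- off / (2 * rs)
  diag(p) <- 0.5
  dimnames(p) <- dimnames(w)
  p
}

local_kernel <- function(w, k) {
  n <- nrow(w)
  off <- w
  diag(off) <- 0
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    top <- order(-off[i, ], seq_len(n))[seq_len(k)]
    top <- top[off[i, top] > 0]
    if (length(top) == 0) {
      s[i, i] <- 1            # isolated node keeps its own mass
    } else {
      s[i, top] <- off[i, top] / sum(off[i, top])
    }
  }
  s
}

#' Fuse normalised affinity networks by cross-diffusion
#'
#' Iterates the SNF update for every view `v`:
#' `P^(v) <- S^(v) %*% mean_{u != v}(P^(u)) %*% t(S^(v))`, then
#' re-symmetrises `(P + t(P))/2` and re-applies the mass-preserving row
#' normalisation. After `t_max` iterations the fused network is the
#' view-average of the status kernels, symmetrised. The max-absolute change
#' per iteration is recorded as a convergence diagnostic.
#'
#' @param state An `"snf_state"` from [normalize_kernels()].
#' @param t_max Number of diffusion iterations (default 20).
#' @return An [affinity_graph()] with modality `"fused"`; attribute
#'   `convergence` holds the per-iteration max-abs change.
#' @export
snf_fuse <- function(state, t_max = 20) {
  stopifnot(inherits(state, "snf_state"), t_max >= 1)
  P <- state$P
  S <- state$S
  m <- length(P)
  change <- numeric(t_max)
  for (t in seq_len(t_max)) {
    prev <- P
    newP <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, prev[-v]) / (m - 1)
      p <- S[[v]] %*% others %*% t(S[[v]])
      p <- (p + t(p)) / 2
      newP[[v]] <- status_kernel(p)
    }
    P <- newP
    if (any(!vapply(P, function(p) all(is.finite(p)), logical(1))))
      stop(sprintf("non-finite SNF kernel at iteration %d", t))
    change[t] <- max(vapply(seq_len(m),
                            function(v) max(abs(P[[v]] - prev[[v]])),
                            numeric(1)))
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(state$sample_ids, state$sample_ids)
  g <- affinity_graph(fused, state$k, "fused")
  attr(g, "convergence") <- change
  g
}

#' Build per-omics graphs and their SNF consensus in one call
#'
#' @param dataset A preprocessed [multiomics_dataset()] (no missing values);
#'   features are cohort-standardised before distances are computed.
#' @param k Neighbour count (default 20).
#' @param mu Kernel bandwidth multiplier (default 0.5).
#' @param t_max SNF iterations (default 20).
#' @param metric Distance metric (default `"sqeuclidean"`).
#' @return List with `graphs` (per-modality [affinity_graph()]s) and
#'   `fused` (the consensus [affinity_graph()]).
#' @export
build_patient_network <- function(dataset, k = 20, mu = 0.5, t_max = 20,
                                  metric = "sqeuclidean") {
  graphs <- lapply(dataset$omics, function(m)
    build_affinity(standardize_features(m), k = k, mu = mu, metric = metric))
  fused <- snf_fuse(normalize_kernels(graphs, k), t_max)
  list(graphs = graphs, fused = fused)
}
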