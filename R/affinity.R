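# Patient-patient affinity graphs: pairwise distances, a locally-scaled
# Gaussian kernel, and k-nearest-neighbour sparsification.

#' Pairwise patient distances
#'
#' @param x An [omics_matrix()] or plain numeric matrix (samples in rows,
#'   no missing values).
#' @param metric `"sqeuclidean"` (squared Euclidean, default) or
#'   `"euclidean"`.
#' @return Symmetric `n x n` distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(x, metric = c("sqeuclidean", "euclidean")) {
  metric <- match.arg(metric)
  v <- if (inherits(x, "omics_matrix")) x$values else x
  if (nrow(v) < 2) stop("need at least 2 samples")
  if (anyNA(v)) stop("missing values present; run filter_and_impute() first")
  sq <- rowSums(v * v)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(v)
  d[d < 0] <- 0                      # numeric guard
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (metric == "euclidean") d <- sqrt(d)
  rownames(d) <- colnames(d) <- rownames(v)
  d
}

#' Locally-scaled Gaussian kernel affinity
#'
#' Converts distances to similarities `s_ij = exp(-d_ij / (2 * mu * eps_ij))`
#' with a locally adaptive bandwidth
#' `eps_ij = (mean_kNN_dist(i) + mean_kNN_dist(j) + d_ij) / 3`, where
#' `mean_kNN_dist(i)` is the mean distance from `i` to its `k` nearest
#' neighbours. This is the similarity-network-fusion form of the Gaussian
#' kernel: the per-modality scale parameter is resolved locally per pair
#' rather than as a single global bandwidth, governed by `mu`. All-identical
#' points would give a zero bandwidth; a small floor (1e-12) guards the
#' division.
#'
#' @param distances Symmetric distance matrix from [pairwise_distance()].
#' @param mu Bandwidth multiplier, > 0 (default 0.5).
#' @param k Neighbour count for the local scale, `1 <= k < n` (default 20).
#' @return Symmetric affinity matrix with values in `(0, 1]` and unit
#'   diagonal.
#' @export
gaussian_affinity <- function(distances, mu = 0.5, k = 20) {
  n <- nrow(distances)
  stopifnot(mu > 0, k >= 1, k < n)
  offdiag <- distances
  diag(offdiag) <- NA
  mean_knn <- apply(offdiag, 1, function(r) mean(sort(r[!is.na(r)])[seq_len(k)]))
  eps <- (outer(mean_knn, mean_knn, "+") + distances) / 3
  eps <- pmax(eps, 1e-12)
  s <- exp(-distances / (2 * mu * eps))
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- dimnames(distances)
  s
}

#' Sparsify an affinity matrix to a k-nearest-neighbour graph
#'
#' Per row, the `k` largest off-diagonal similarities are retained and the
#' rest zeroed (ties broken by lower sample index, for reproducibility); the
#' result is symmetrised by the elementwise maximum so every retained edge
#' survives as an undirected edge. The unit diagonal is kept. A warning
#' reports the connected-component count when the graph is disconnected.
#'
#' @param affinity Symmetric affinity matrix (e.g. from
#'   [gaussian_affinity()]) with sample ids as dimnames.
#' @param k Neighbours kept per row, `1 <= k < n` (default 20).
#' @param modality Modality tag for the resulting graph.
#' @return An [affinity_graph()].
#' @export
knn_sparsify <- function(affinity, k = 20, modality = "unknown") {
  n <- nrow(affinity)
  stopifnot(k >= 1, k < n)
  w <- matrix(0, n, n, dimnames = dimnames(affinity))
  for (i in seq_len(n)) {
    row <- affinity[i, ]
    row[i] <- -Inf
    top <- order(-row, seq_len(n))[seq_len(k)]   # stable: lower index wins ties
    w[i, top] <- affinity[i, top]
  }
  w <- pmax(w, t(w))
  diag(w) <- diag(affinity)
  g <- affinity_graph(w, k, modality)
  nc <- n_components(w)
  if (nc > 1)
    warning(sprintf("%s k-NN graph is disconnected (%d components)",
                    modality, nc))
  g
}

# connected components of a weighted graph by BFS on the nonzero off-diagonal
n_components <- function(w) {
  n <- nrow(w)
  adj <- w > 0
  diag(adj) <- FALSE
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

#' Build a sparsified affinity graph from one omics matrix
#'
#' Convenience chain of [pairwise_distance()], [gaussian_affinity()] and
#' [knn_sparsify()].
#'
#' @param x An [omics_matrix()] or numeric matrix without missing values.
#' @param k Neighbour count (default 20).
#' @param mu Kernel bandwidth multiplier (default 0.5).
#' @param metric Distance metric (default `"sqeuclidean"`).
#' @return An [affinity_graph()].
#' @export
build_affinity <- function(x, k = 20, mu = 0.5, metric = "sqeuclidean") {
  modality <- if (inherits(x, "omics_matrix")) x$modality else "unknown"
  d <- pairwise_distance(x, metric)
  knn_sparsify(gaussian_affinity(d, mu, k), k, modality)
}

#' Write an affinity graph as a dense matrix or edge list
#'
#' @param graph An [affinity_graph()].
#' @param path Output path.
#' @param format `"matrix"` (dense, header ids) or `"edges"`
#'   (`id_a`, `id_b`, `weight`, upper triangle only).
#' @return `path`, invisibly.
#' @export
write_affinity <- function(graph, path, format = c("matrix", "edges")) {
  format <- match.arg(format)
  w <- graph$weights
  if (format == "matrix") {
    out <- cbind(SAMPLE_ID = rownames(w),
                 matrix(formatC(w, digits = 17, format = "g"),
                        nrow(w), dimnames = list(NULL, colnames(w))))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    out <- data.frame(id_a = rownames(w)[idx[, 1]],
                      id_b = colnames(w)[idx[, 2]],
                      weight = w[idx])
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
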