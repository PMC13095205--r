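# Jumping-knowledge graph-convolution branches. Each branch runs L
# GCN-style propagation steps (symmetric-normalised adjacency with
# self-loops) over a patient graph and aggregates the representations of
# layers 0..L ("cat" by default), so shallow and deep neighbourhood scales
# both reach the classifier and deep stacks do not over-smooth. Branches are
# trained transductively with an auxiliary softmax head on training nodes;
# the pre-head aggregated representation is the branch's latent embedding.

#' Configuration for a jumping-knowledge graph branch
#'
#' @param n_layers Number of propagation layers `L` (default 2).
#' @param hidden_dim Hidden width per layer (default 100).
#' @param mode Layer aggregation: `"cat"` (concatenate layers 0..L, default),
#'   `"max"` (elementwise maximum) or `"last"` (final layer only, i.e. a
#'   plain GCN of the same depth - the ablation baseline).
#' @param dropout Dropout rate on hidden layers during training (default 0.5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 150).
#' @param seed Integer seed.
#' @return An object of class `"jk_config"`.
#' @export
jk_config <- function(n_layers = 2, hidden_dim = 100,
                      mode = c("cat", "max", "last"),
                      dropout = 0.5, learning_rate = 0.001, epochs = 150,
                      seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_layers >= 1, hidden_dim >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, epochs >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim), mode = mode,
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "jk_config")
}

#' Symmetric-normalised adjacency with self-loops
#'
#' `D^{-1/2} (A + I) D^{-1/2}` on the graph's (weighted) adjacency; any
#' existing diagonal is replaced by the unit self-loop.
#'
#' @param graph An [affinity_graph()] or plain symmetric weight matrix.
#' @return Dense normalised adjacency matrix.
#' @export
norm_adjacency <- function(graph) {
  a <- if (inherits(graph, "affinity_graph")) graph$weights else graph
  diag(a) <- 0
  a <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(a))
  a * outer(dinv, dinv)
}

#' One jumping-knowledge propagation step
#'
#' `h' = ReLU(Ahat %*% h %*% W)` where `Ahat` is the symmetric-normalised
#' adjacency with self-loops: each node averages its (self-inclusive)
#' neighbourhood, applies the layer's linear map and a ReLU.
#'
#' @param h_prev Node representations (`n x d`).
#' @param adjacency An [affinity_graph()] or a pre-normalised adjacency
#'   matrix from [norm_adjacency()].
#' @param W Weight matrix (`d x d'`).
#' @param b Optional bias row vector.
#' @return Updated representations (`n x d'`).
#' @export
jk_layer <- function(h_prev, adjacency, W, b = NULL) {
  ahat <- if (inherits(adjacency, "affinity_graph")) norm_adjacency(adjacency)
          else adjacency
  z <- (ahat %*% h_prev) %*% W
  if (!is.null(b)) z <- add_bias(z, b)
  stop_if_nonfinite(z, "jumping-knowledge layer output")
  relu(z)
}

#' Aggregate layer-wise representations
#'
#' @param layer_outputs List of matrices `h^(0) .. h^(L)` with equal row
#'   counts (`h^(0)` is the width-standardised input projection).
#' @param mode `"cat"` (column-wise concatenation), `"max"` (elementwise
#'   maximum; requires equal widths) or `"last"` (final layer only).
#' @return The aggregated representation matrix.
#' @export
jk_aggregate <- function(layer_outputs, mode = c("cat", "max", "last")) {
  mode <- match.arg(mode)
  stopifnot(length(layer_outputs) >= 1)
  if (mode == "cat") return(do.call(cbind, layer_outputs))
  if (mode == "last") return(layer_outputs[[length(layer_outputs)]])
  widths <- vapply(layer_outputs, ncol, integer(1))
  if (length(unique(widths)) != 1)
    stop("max-mode aggregation requires equal layer widths")
  Reduce(pmax, layer_outputs)
}

jk_init_params <- function(p, hidden, n_layers, n_classes, mode) {
  params <- list(W0 = glorot(p, hidden), b0 = matrix(0, 1, hidden))
  for (l in seq_len(n_layers)) {
    params[[paste0("W", l)]] <- glorot(hidden, hidden)
    params[[paste0("b", l)]] <- matrix(0, 1, hidden)
  }
  emb_dim <- if (mode == "cat") (n_layers + 1) * hidden else hidden
  params$Wc <- glorot(emb_dim, n_classes)
  params$bc <- matrix(0, 1, n_classes)
  params
}

# forward pass; drop_fn(NULL) means no dropout. Returns layers h0..hL,
# their propagated inputs P_l = Ahat %*% drop(h_{l-1}), masks, H, logits.
jk_forward <- function(params, X, ahat, n_layers, mode, dropout, training) {
  n <- nrow(X)
  hs <- vector("list", n_layers + 1)
  masks <- vector("list", n_layers)
  props <- vector("list", n_layers)
  hs[[1]] <- add_bias(X %*% params$W0, params$b0)
  for (l in seq_len(n_layers)) {
    inp <- hs[[l]]
    if (training && dropout > 0) {
      masks[[l]] <- dropout_mask(n, ncol(inp), dropout)
      inp <- inp * masks[[l]]
    }
    props[[l]] <- ahat %*% inp
    hs[[l + 1]] <- relu(add_bias(props[[l]] %*% params[[paste0("W", l)]],
                                 params[[paste0("b", l)]]))
  }
  H <- jk_aggregate(hs, mode)
  Hmask <- NULL
  Hd <- H
  if (training && dropout > 0) {
    Hmask <- dropout_mask(n, ncol(H), dropout)
    Hd <- H * Hmask
  }
  logits <- add_bias(Hd %*% params$Wc, params$bc)
  list(hs = hs, masks = masks, props = props, H = H, Hd = Hd,
       Hmask = Hmask, logits = logits)
}

# split the gradient of the aggregated representation back into per-layer
# gradients according to the aggregation mode
jk_split_grad <- function(dH, hs, mode) {
  Lp1 <- length(hs)
  if (mode == "cat") {
    out <- vector("list", Lp1)
    offset <- 0
    for (l in seq_len(Lp1)) {
      w <- ncol(hs[[l]])
      out[[l]] <- dH[, offset + seq_len(w), drop = FALSE]
      offset <- offset + w
    }
    return(out)
  }
  if (mode == "last") {
    out <- lapply(hs, function(h) h * 0)
    out[[Lp1]] <- dH
    return(out)
  }
  # max: route each element's gradient to the first layer achieving the max
  M <- Reduce(pmax, hs)
  out <- vector("list", Lp1)
  taken <- matrix(FALSE, nrow(dH), ncol(dH))
  for (l in seq_len(Lp1)) {
    sel <- (hs[[l]] == M) & !taken
    out[[l]] <- dH * sel
    taken <- taken | sel
  }
  out
}

#' Train one jumping-knowledge branch transductively
#'
#' Full-graph forward passes with the cross-entropy loss masked to training
#' nodes; an auxiliary linear softmax head supervises the branch, and the
#' pre-head aggregated representation of every node is returned as the
#' branch embedding. Deterministic given `config$seed`.
#'
#' @param features Numeric matrix `n x p` of node features, rows aligned
#'   with the graph's sample ids.
#' @param graph An [affinity_graph()].
#' @param labels Factor of node labels (all nodes; only training nodes enter
#'   the loss).
#' @param train_mask Logical vector marking training nodes.
#' @param config A [jk_config()].
#' @param branch Name used for the embedding source tag and the seed
#'   derivation.
#' @return A [latent_embedding()] (source `"JK_<branch>"`); attributes
#'   `report` (per-epoch loss, final train accuracy) and `params` (trained
#'   parameters).
#' @export
train_jk_branch <- function(features, graph, labels, train_mask,
                            config = jk_config(), branch = "branch") {
  stopifnot(nrow(features) == length(labels), length(train_mask) == length(labels))
  labels <- as.factor(labels)
  if (length(unique(labels[train_mask])) < 2)
    stop("training mask covers a single class")
  n_classes <- nlevels(labels)
  ahat <- norm_adjacency(graph)
  Y <- one_hot(labels, n_classes)
  n_train <- sum(train_mask)
  set.seed(stage_seed(config$seed, paste0("jk_", branch)))
  params <- jk_init_params(ncol(features), config$hidden_dim,
                           config$n_layers, n_classes, config$mode)
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    fw <- jk_forward(params, features, ahat, config$n_layers, config$mode,
                     config$dropout, training = TRUE)
    probs <- softmax_rows(fw$logits)
    loss <- masked_cross_entropy(probs, Y, train_mask)
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", epoch))
    history[epoch] <- loss
    dlogits <- (probs - Y) / n_train
    dlogits[!train_mask, ] <- 0
    g <- list()
    g$Wc <- crossprod(fw$Hd, dlogits)
    g$bc <- matrix(colSums(dlogits), 1)
    dH <- dlogits %*% t(params$Wc)
    if (!is.null(fw$Hmask)) dH <- dH * fw$Hmask
    dhs <- jk_split_grad(dH, fw$hs, config$mode)
    for (l in rev(seq_len(config$n_layers))) {
      dz <- dhs[[l + 1]] * (fw$hs[[l + 1]] > 0)
      g[[paste0("W", l)]] <- crossprod(fw$props[[l]], dz)
      g[[paste0("b", l)]] <- matrix(colSums(dz), 1)
      dinp <- (ahat %*% dz) %*% t(params[[paste0("W", l)]])
      if (!is.null(fw$masks[[l]])) dinp <- dinp * fw$masks[[l]]
      dhs[[l]] <- dhs[[l]] + dinp
    }
    g$W0 <- crossprod(features, dhs[[1]])
    g$b0 <- matrix(colSums(dhs[[1]]), 1)
    step <- adam_step(params, g, opt, config$learning_rate)
    params <- step$params
    opt <- step$state
  }
  fw <- jk_forward(params, features, ahat, config$n_layers, config$mode,
                   config$dropout, training = FALSE)
  pred <- max.col(fw$logits, ties.method = "first")
  train_acc <- mean(pred[train_mask] == as.integer(labels)[train_mask])
  emb <- fw$H
  rownames(emb) <- sample_ids(graph)
  colnames(emb) <- paste0(branch, "_", seq_len(ncol(emb)))
  out <- latent_embedding(emb, paste0("JK_", branch))
  attr(out, "report") <- list(loss = history, train_accuracy = train_acc,
                              predictions = pred)
  attr(out, "params") <- params
  out
}

#' Train the per-omics branches (raw features + per-omics graphs)
#'
#' One jumping-knowledge branch per modality, each on that modality's
#' (standardised) feature matrix and affinity graph.
#'
#' @param x_list Named list of standardised feature matrices.
#' @param graphs Named list of [affinity_graph()]s, aligned with `x_list`.
#' @param labels Factor of node labels.
#' @param train_mask Logical training mask.
#' @param config A [jk_config()]; `config$seed` fans out per branch.
#' @return Named list of [latent_embedding()]s, one per modality.
#' @export
run_input1 <- function(x_list, graphs, labels, train_mask,
                       config = jk_config()) {
  stopifnot(identical(names(x_list), names(graphs)))
  out <- lapply(names(x_list), function(nm)
    train_jk_branch(x_list[[nm]], graphs[[nm]], labels, train_mask,
                    config, branch = nm))
  names(out) <- names(x_list)
  out
}

#' Train the patient-level branch (autoencoder latent + fused graph)
#'
#' @param ae_latent A [latent_embedding()] from [fit_autoencoder()].
#' @param fused The fused [affinity_graph()] from [snf_fuse()].
#' @param labels Factor of node labels.
#' @param train_mask Logical training mask.
#' @param config A [jk_config()].
#' @return A [latent_embedding()] (source `"JK_patient"`).
#' @export
run_input2 <- function(ae_latent, fused, labels, train_mask,
                       config = jk_config()) {
  stopifnot(identical(sample_ids(ae_latent), sample_ids(fused)))
  train_jk_branch(ae_latent$values, fused, labels, train_mask,
                  config, branch = "patient")
}
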