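# Graph attention classifier over the concatenated branch embeddings, with
# the fused patient network as graph structure: one multi-head attention
# layer (head outputs concatenated, ELU) followed by a linear softmax head,
# trained transductively with masked cross-entropy.

#' Configuration for the graph attention classifier
#'
#' @param hidden_dim Per-head hidden width (default 100).
#' @param heads Number of attention heads (default 2; head outputs are
#'   concatenated).
#' @param leaky_slope Negative slope of the attention LeakyReLU
#'   (default 0.2).
#' @param dropout Dropout rate on input and hidden representations during
#'   training (default 0.5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 150).
#' @param seed Integer seed.
#' @return An object of class `"gat_config"`.
#' @export
gat_config <- function(hidden_dim = 100, heads = 2, leaky_slope = 0.2,
                       dropout = 0.5, learning_rate = 0.001, epochs = 150,
                       seed = 1) {
  stopifnot(hidden_dim >= 1, heads >= 1, leaky_slope > 0, leaky_slope < 1,
            dropout >= 0, dropout < 1, learning_rate > 0, epochs >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 heads = as.integer(heads), leaky_slope = leaky_slope,
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "gat_config")
}

#' Concatenate latent embeddings column-wise
#'
#' @param parts List of [latent_embedding()]s with identical sample ids in
#'   identical order.
#' @return A [latent_embedding()] with source `"final"`.
#' @export
concat_embeddings <- function(parts) {
  stopifnot(length(parts) >= 1)
  ids <- sample_ids(parts[[1]])
  for (p in parts)
    if (!identical(sample_ids(p), ids))
      stop("embeddings to concatenate have misaligned sample ids")
  latent_embedding(do.call(cbind, lapply(parts, function(p) p$values)),
                   "final")
}

gat_init_params <- function(d_in, hidden, heads, n_classes) {
  params <- list()
  for (h in seq_len(heads)) {
    params[[paste0("W", h)]] <- glorot(d_in, hidden)
    params[[paste0("a1_", h)]] <- matrix(glorot(2 * hidden, 1)[seq_len(hidden)], ncol = 1)
    params[[paste0("a2_", h)]] <- matrix(glorot(2 * hidden, 1)[hidden + seq_len(hidden)], ncol = 1)
  }
  params$Wc <- glorot(heads * hidden, n_classes)
  params$bc <- matrix(0, 1, n_classes)
  params
}

# neighbourhood mask: nonzero fused-graph edges plus guaranteed self-loops
gat_mask <- function(graph) {
  a <- if (inherits(graph, "affinity_graph")) graph$weights else graph
  m <- a > 0
  diag(m) <- TRUE
  m
}

# one multi-head attention layer; returns per-head alphas and pre-activation
gat_layer_forward <- function(params, H, mask, heads, slope) {
  out <- vector("list", heads)
  cache <- vector("list", heads)
  for (h in seq_len(heads)) {
    Wh <- H %*% params[[paste0("W", h)]]
    f1 <- as.numeric(Wh %*% params[[paste0("a1_", h)]])
    f2 <- as.numeric(Wh %*% params[[paste0("a2_", h)]])
    e <- outer(f1, rep(1, length(f2))) + outer(rep(1, length(f1)), f2)
    lre <- leaky_relu(e, slope)
    lre[!mask] <- -Inf
    alpha <- softmax_rows(lre)
    alpha[!mask] <- 0
    out[[h]] <- alpha %*% Wh
    cache[[h]] <- list(Wh = Wh, e = e, alpha = alpha)
  }
  list(Z = do.call(cbind, out), cache = cache)
}

#' One graph attention layer (forward pass)
#'
#' Computes, per head, attention logits
#' `e_ij = LeakyReLU(a^T [W h_i || W h_j])` over each node's self-inclusive
#' neighbourhood, softmax-normalises them into coefficients `alpha_ij`
#' (rows sum to 1), and aggregates `h_i' = ELU(sum_j alpha_ij W h_j)`;
#' multi-head outputs are concatenated.
#'
#' @param h Node feature matrix (`n x d`).
#' @param graph An [affinity_graph()] (self-loops are guaranteed).
#' @param params Parameter list from a trained model, or `NULL` to draw a
#'   fresh Glorot initialisation (seeded externally).
#' @param config A [gat_config()].
#' @return List with `h_next` (`n x heads*hidden_dim`) and `attention`
#'   (list of per-head `n x n` coefficient matrices).
#' @export
gat_attention <- function(h, graph, params = NULL, config = gat_config()) {
  mask <- gat_mask(graph)
  if (is.null(params))
    params <- gat_init_params(ncol(h), config$hidden_dim, config$heads, 2)
  fw <- gat_layer_forward(params, h, mask, config$heads, config$leaky_slope)
  list(h_next = elu(fw$Z),
       attention = lapply(fw$cache, `[[`, "alpha"))
}

# full training of the attention classifier on one train mask; returns
# predictions for all nodes, trained params and attention matrices
gat_fit <- function(embedding, graph, labels, train_mask, config,
                    stage = "gat") {
  H0 <- if (inherits(embedding, "latent_embedding")) embedding$values else embedding
  labels <- as.factor(labels)
  n_classes <- nlevels(labels)
  n <- nrow(H0)
  stopifnot(length(labels) == n, length(train_mask) == n)
  if (length(unique(labels[train_mask])) < 2)
    stop("training mask covers a single class")
  mask <- gat_mask(graph)
  Y <- one_hot(labels, n_classes)
  n_train <- sum(train_mask)
  slope <- config$leaky_slope
  set.seed(stage_seed(config$seed, stage))
  params <- gat_init_params(ncol(H0), config$hidden_dim, config$heads, n_classes)
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    Hin <- H0
    in_mask <- NULL
    if (config$dropout > 0) {
      in_mask <- dropout_mask(n, ncol(H0), config$dropout)
      Hin <- H0 * in_mask
    }
    fw <- gat_layer_forward(params, Hin, mask, config$heads, slope)
    act <- elu(fw$Z)
    hid_mask <- NULL
    actd <- act
    if (config$dropout > 0) {
      hid_mask <- dropout_mask(n, ncol(act), config$dropout)
      actd <- act * hid_mask
    }
    logits <- add_bias(actd %*% params$Wc, params$bc)
    probs <- softmax_rows(logits)
    loss <- masked_cross_entropy(probs, Y, train_mask)
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", epoch))
    history[epoch] <- loss
    dlogits <- (probs - Y) / n_train
    dlogits[!train_mask, ] <- 0
    g <- list()
    g$Wc <- crossprod(actd, dlogits)
    g$bc <- matrix(colSums(dlogits), 1)
    dact <- dlogits %*% t(params$Wc)
    if (!is.null(hid_mask)) dact <- dact * hid_mask
    dZ <- dact * elu_grad(act)
    hidden <- config$hidden_dim
    for (h in seq_len(config$heads)) {
      ch <- fw$cache[[h]]
      dOut <- dZ[, (h - 1) * hidden + seq_len(hidden), drop = FALSE]
      dWh <- crossprod(ch$alpha, dOut)
      dalpha <- dOut %*% t(ch$Wh)
      dalpha[!mask] <- 0
      de <- ch$alpha * (dalpha - rowSums(ch$alpha * dalpha))
      de <- de * ifelse(ch$e > 0, 1, slope)
      de[!mask] <- 0
      df1 <- rowSums(de)
      df2 <- colSums(de)
      g[[paste0("a1_", h)]] <- crossprod(ch$Wh, df1)
      g[[paste0("a2_", h)]] <- crossprod(ch$Wh, df2)
      dWh <- dWh + outer(df1, as.numeric(params[[paste0("a1_", h)]])) +
        outer(df2, as.numeric(params[[paste0("a2_", h)]]))
      g[[paste0("W", h)]] <- crossprod(Hin, dWh)
    }
    step <- adam_step(params, g, opt, config$learning_rate)
    params <- step$params
    opt <- step$state
  }
  fw <- gat_layer_forward(params, H0, mask, config$heads, slope)
  logits <- add_bias(elu(fw$Z) %*% params$Wc, params$bc)
  probs <- softmax_rows(logits)
  pred <- factor(levels(labels)[max.col(probs, ties.method = "first")],
                 levels = levels(labels))
  list(predictions = pred, probabilities = probs, params = params,
       attention = lapply(fw$cache, `[[`, "alpha"), loss = history)
}

#' Train the graph attention classifier over a split plan
#'
#' For each test fold of `split`, trains the classifier on the remaining
#' nodes (transductive, masked cross-entropy), predicts the test-fold nodes,
#' and scores macro precision/recall/F1 per fold. Deterministic given
#' `config$seed` (each fold derives its own stage seed).
#'
#' @param embedding A [latent_embedding()] (typically the concatenated
#'   branch embedding from [concat_embeddings()]).
#' @param graph The fused [affinity_graph()] used as graph structure.
#' @param labels Factor of node labels.
#' @param split A [make_splits()] plan, or a logical training mask for a
#'   single fit (then predictions for all nodes are returned without
#'   metrics).
#' @param config A [gat_config()].
#' @return For a split plan: list with `predictions` (data.frame of
#'   `sample_id`, `fold`, `true`, `predicted` and class probabilities) and
#'   `metrics` (a [metrics_report()]). For a mask: the single-fit list from
#'   the internal trainer (predictions, probabilities, params, attention,
#'   loss).
#' @export
train_gat <- function(embedding, graph, labels, split,
                      config = gat_config()) {
  labels <- as.factor(labels)
  if (is.logical(split))
    return(gat_fit(embedding, graph, labels, split, config))
  stopifnot(inherits(split, "split_plan"))
  ids <- sample_ids(embedding)
  per_fold <- vector("list", length(split$test_folds))
  rows <- vector("list", length(split$test_folds))
  for (i in seq_along(split$test_folds)) {
    f <- split$test_folds[i]
    test <- split$fold_of == f
    fit <- gat_fit(embedding, graph, labels, !test, config,
                   stage = paste0("gat_fold", f))
    per_fold[[i]] <- macro_metrics(labels[test], fit$predictions[test])
    probs <- fit$probabilities[test, , drop = FALSE]
    colnames(probs) <- paste0("p_", levels(labels))
    rows[[i]] <- data.frame(sample_id = ids[test], fold = f,
                            true = labels[test],
                            predicted = fit$predictions[test],
                            probs, row.names = NULL, check.names = FALSE)
  }
  list(predictions = do.call(rbind, rows),
       metrics = metrics_report(per_fold, nlevels(labels)))
}
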