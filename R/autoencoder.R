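# Multimodal autoencoder: one encoder and decoder per omics modality around a
# shared latent layer, trained by minimising a weighted sum of per-modality
# reconstruction errors. Dense base-R implementation with manual
# backpropagation and Adam.

#' Configuration for the multimodal autoencoder
#'
#' @param latent_dim Shared latent dimension (default 100, commensurate with
#'   the graph-branch hidden width).
#' @param loss_weights Named per-modality reconstruction weights, summing
#'   to 1. Defaults to `c(CNA = 0.2, MET = 0.2, mRNA = 0.3, RPPA = 0.3)`:
#'   the transcriptomic and proteomic layers carry slightly more weight on
#'   prior grounds.
#' @param hidden_cap Width cap for the per-modality encoder/decoder hidden
#'   layer: a modality with `p` features gets `min(p, hidden_cap)` units
#'   (default 500).
#' @param epochs Training epochs (default 150).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param seed Integer seed for initialisation.
#' @return An object of class `"ae_config"`.
#' @export
ae_config <- function(latent_dim = 100,
                      loss_weights = c(CNA = 0.2, MET = 0.2, mRNA = 0.3, RPPA = 0.3),
                      hidden_cap = 500, epochs = 150, learning_rate = 0.001,
                      seed = 1) {
  if (any(loss_weights < 0)) stop("loss weights must be non-negative")
  if (abs(sum(loss_weights) - 1) > 1e-12) stop("loss weights must sum to 1")
  stopifnot(latent_dim >= 1, epochs >= 1, learning_rate > 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 loss_weights = loss_weights,
                 hidden_cap = as.integer(hidden_cap),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ae_config")
}

#' Weighted multimodal reconstruction loss
#'
#' `sum_m w_m * MSE(x_m, xhat_m)` with per-modality mean squared error.
#'
#' @param x List of observed matrices, one per modality.
#' @param x_hat List of reconstructions, same shapes.
#' @param weights Per-modality weights (same length, summing to 1).
#' @return The scalar weighted loss.
#' @export
ae_loss <- function(x, x_hat, weights) {
  stopifnot(length(x) == length(x_hat), length(x) == length(weights))
  total <- 0
  for (m in seq_along(x)) {
    if (!identical(dim(x[[m]]), dim(x_hat[[m]])))
      stop("shape mismatch in modality ", m)
    total <- total + weights[[m]] * mean((x[[m]] - x_hat[[m]])^2)
  }
  total
}

#' Initialise a multimodal autoencoder
#'
#' Architecture: per modality `m`, encoder `p_m -> h_m` (ReLU) with
#' `h_m = min(p_m, hidden_cap)`; the encoder outputs are concatenated and
#' linearly projected to the shared latent of width `latent_dim`; per
#' modality, decoder `latent -> h_m` (ReLU) `-> p_m` (linear).
#' Initialisation is Glorot-uniform and deterministic given `config$seed`.
#'
#' @param config An [ae_config()].
#' @param feature_dims Integer vector of per-modality feature counts.
#' @return Model handle: list with `params`, `feature_dims`, `hidden_dims`,
#'   `config`.
#' @export
build_multimodal_ae <- function(config, feature_dims) {
  stopifnot(inherits(config, "ae_config"), length(feature_dims) >= 1)
  if (config$latent_dim > min(feature_dims))
    warning("latent_dim exceeds the smallest modality's feature count")
  set.seed(stage_seed(config$seed, "ae_init"))
  hidden <- pmin(feature_dims, config$hidden_cap)
  params <- list()
  for (m in seq_along(feature_dims)) {
    params[[paste0("We", m)]] <- glorot(feature_dims[m], hidden[m])
    params[[paste0("be", m)]] <- matrix(0, 1, hidden[m])
    params[[paste0("Wd1_", m)]] <- glorot(config$latent_dim, hidden[m])
    params[[paste0("bd1_", m)]] <- matrix(0, 1, hidden[m])
    params[[paste0("Wd2_", m)]] <- glorot(hidden[m], feature_dims[m])
    params[[paste0("bd2_", m)]] <- matrix(0, 1, feature_dims[m])
  }
  params$Wp <- glorot(sum(hidden), config$latent_dim)
  params$bp <- matrix(0, 1, config$latent_dim)
  list(params = params, feature_dims = feature_dims, hidden_dims = hidden,
       config = config)
}

add_bias <- function(x, b) sweep(x, 2, as.numeric(b), "+")

ae_forward <- function(model, x_list) {
  p <- model$params
  M <- length(x_list)
  H <- vector("list", M)
  for (m in seq_len(M))
    H[[m]] <- relu(add_bias(x_list[[m]] %*% p[[paste0("We", m)]],
                            p[[paste0("be", m)]]))
  Hcat <- do.call(cbind, H)
  Z <- add_bias(Hcat %*% p$Wp, p$bp)
  D <- Xhat <- vector("list", M)
  for (m in seq_len(M)) {
    D[[m]] <- relu(add_bias(Z %*% p[[paste0("Wd1_", m)]], p[[paste0("bd1_", m)]]))
    Xhat[[m]] <- add_bias(D[[m]] %*% p[[paste0("Wd2_", m)]], p[[paste0("bd2_", m)]])
  }
  list(H = H, Hcat = Hcat, Z = Z, D = D, Xhat = Xhat)
}

ae_backward <- function(model, x_list, fw) {
  p <- model$params
  w <- model$config$loss_weights
  M <- length(x_list)
  n <- nrow(x_list[[1]])
  g <- list()
  dZ <- matrix(0, n, ncol(fw$Z))
  for (m in seq_len(M)) {
    dXhat <- 2 * w[[m]] * (fw$Xhat[[m]] - x_list[[m]]) /
      (n * ncol(x_list[[m]]))
    g[[paste0("Wd2_", m)]] <- crossprod(fw$D[[m]], dXhat)
    g[[paste0("bd2_", m)]] <- matrix(colSums(dXhat), 1)
    dD <- (dXhat %*% t(p[[paste0("Wd2_", m)]])) * (fw$D[[m]] > 0)
    g[[paste0("Wd1_", m)]] <- crossprod(fw$Z, dD)
    g[[paste0("bd1_", m)]] <- matrix(colSums(dD), 1)
    dZ <- dZ + dD %*% t(p[[paste0("Wd1_", m)]])
  }
  g$Wp <- crossprod(fw$Hcat, dZ)
  g$bp <- matrix(colSums(dZ), 1)
  dHcat <- dZ %*% t(p$Wp)
  offset <- 0
  for (m in seq_len(M)) {
    hm <- model$hidden_dims[m]
    dH <- dHcat[, offset + seq_len(hm), drop = FALSE] * (fw$H[[m]] > 0)
    g[[paste0("We", m)]] <- crossprod(x_list[[m]], dH)
    g[[paste0("be", m)]] <- matrix(colSums(dH), 1)
    offset <- offset + hm
  }
  g
}

#' Train the multimodal autoencoder and embed every sample
#'
#' Trains full-batch with Adam on the training rows (all rows by default),
#' minimising the weighted reconstruction loss of [ae_loss()], then encodes
#' every sample into the shared latent space. Deterministic given
#' `config$seed`.
#'
#' @param x_list Named list of standardised feature matrices (one per
#'   modality, shared row order, no missing values), or a
#'   [multiomics_dataset()] (whose matrices are then cohort-standardised).
#' @param config An [ae_config()].
#' @param train_ids Optional character vector (or logical/integer index) of
#'   rows to train on; all rows are embedded regardless.
#' @return A [latent_embedding()] with source `"AE"`; attribute
#'   `loss_history` records the weighted training loss per epoch, attribute
#'   `params` the trained parameters.
#' @export
fit_autoencoder <- function(x_list, config = ae_config(), train_ids = NULL) {
  if (inherits(x_list, "multiomics_dataset"))
    x_list <- lapply(x_list$omics, function(m) standardize_features(m)$values)
  stopifnot(is.list(x_list), length(x_list) >= 1)
  ids <- rownames(x_list[[1]])
  model <- build_multimodal_ae(config, vapply(x_list, ncol, integer(1)))
  train <- if (is.null(train_ids)) seq_along(ids) else train_ids
  x_train <- lapply(x_list, function(x) x[train, , drop = FALSE])
  opt <- adam_init(model$params)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    fw <- ae_forward(model, x_train)
    loss <- ae_loss(x_train, fw$Xhat, config$loss_weights)
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", epoch))
    history[epoch] <- loss
    grads <- ae_backward(model, x_train, fw)
    step <- adam_step(model$params, grads, opt, config$learning_rate)
    model$params <- step$params
    opt <- step$state
  }
  fw_all <- ae_forward(model, x_list)
  emb <- fw_all$Z
  rownames(emb) <- ids
  colnames(emb) <- paste0("AE", seq_len(ncol(emb)))
  out <- latent_embedding(emb, "AE")
  attr(out, "loss_history") <- history
  attr(out, "params") <- model$params
  out
}
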