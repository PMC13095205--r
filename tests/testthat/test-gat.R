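path3_graph <- function() {
  a <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  affinity_graph(a, k = 1, modality = "fused")
}

test_that("embedding concatenation aligns ids and adds widths", {
  ids <- sprintf("S%02d", 1:6)
  mk <- function(d, src) {
    v <- matrix(rnorm(6 * d), 6, d, dimnames = list(ids, NULL))
    latent_embedding(v, src)
  }
  set.seed(1)
  parts <- list(mk(3, "JK_CNA"), mk(4, "JK_MET"), mk(2, "JK_patient"))
  out <- concat_embeddings(parts)
  expect_equal(ncol(out$values), 9L)
  expect_equal(out$source, "final")
  expect_equal(sample_ids(out), ids)
  expect_equal(out$values[, 1:3], parts[[1]]$values, ignore_attr = TRUE)
  # single part is the identity on values
  one <- concat_embeddings(parts[1])
  expect_equal(one$values, parts[[1]]$values)
  # misalignment is an error
  bad <- mk(2, "x")
  rownames(bad$values) <- rev(ids)
  expect_error(concat_embeddings(list(parts[[1]], bad)), "misaligned")
})

test_that("attention coefficients are a softmax over each neighbourhood", {
  g <- path3_graph()
  set.seed(7)
  h <- matrix(rnorm(6), 3, 2)
  cfg <- gat_config(hidden_dim = 2, heads = 2, dropout = 0)
  set.seed(42)
  out <- gat_attention(h, g, config = cfg)
  for (alpha in out$attention) {
    expect_equal(unname(rowSums(alpha)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(alpha >= 0))
    # node 1 attends only to itself and node 2
    expect_equal(alpha[1, 3], 0)
  }
  expect_equal(dim(out$h_next), c(3L, 4L))
})

test_that("a three-node toy reproduces the hand-computed attention softmax", {
  g <- path3_graph()
  h <- matrix(c(1, 0, -1, 0.5, 1, 0), 3, 2)
  W <- matrix(c(0.1, -0.2, 0.3, 0.05), 2, 2)
  a1 <- matrix(c(0.4, -0.1), 2, 1)
  a2 <- matrix(c(0.2, 0.3), 2, 1)
  params <- list(W1 = W, a1_1 = a1, a2_1 = a2)
  cfg <- gat_config(hidden_dim = 2, heads = 1, leaky_slope = 0.2, dropout = 0)
  out <- gat_attention(h, g, params = params, config = cfg)
  # scalar arithmetic oracle
  Wh <- h %*% W
  f1 <- as.numeric(Wh %*% a1)
  f2 <- as.numeric(Wh %*% a2)
  lrelu <- function(z) ifelse(z > 0, z, 0.2 * z)
  nbrs <- list(c(1, 2), c(1, 2, 3), c(2, 3))
  alpha_hand <- matrix(0, 3, 3)
  for (i in 1:3) {
    e <- vapply(nbrs[[i]], function(j) lrelu(f1[i] + f2[j]), numeric(1))
    alpha_hand[i, nbrs[[i]]] <- exp(e) / sum(exp(e))
  }
  expect_equal(unname(out$attention[[1]]), alpha_hand, tolerance = 1e-12)
  # single-neighbour-free check: aggregation is alpha %*% Wh through ELU
  elu_hand <- function(z) ifelse(z > 0, z, exp(z) - 1)
  expect_equal(unname(out$h_next), elu_hand(alpha_hand %*% Wh),
               tolerance = 1e-12)
})

test_that("uniform features give uniform attention; lone neighbours get weight 1", {
  g <- path3_graph()
  h <- matrix(1, 3, 2)
  set.seed(3)
  out <- gat_attention(h, g, config = gat_config(hidden_dim = 2, heads = 1,
                                                 dropout = 0))
  alpha <- out$attention[[1]]
  expect_equal(unname(alpha[1, 1:2]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(alpha[2, ]), rep(1 / 3, 3), tolerance = 1e-12)

  # an isolated node attends only to its self-loop
  a <- matrix(0, 2, 2, dimnames = list(c("s1", "s2"), c("s1", "s2")))
  g2 <- affinity_graph(a, k = 1, modality = "fused")
  out2 <- gat_attention(matrix(rnorm(4), 2, 2), g2,
                        config = gat_config(hidden_dim = 2, heads = 1,
                                            dropout = 0))
  expect_equal(unname(diag(out2$attention[[1]])), c(1, 1))
})

test_that("a linearly separable embedding on a trivial graph is classified perfectly", {
  n <- 24
  ids <- sprintf("S%02d", 1:n)
  labels <- factor(rep(c("a", "b"), each = n / 2))
  set.seed(5)
  v <- matrix(rnorm(n * 2, mean = ifelse(labels == "a", -6, 6)), n, 2,
              dimnames = list(ids, NULL))
  emb <- latent_embedding(v, "final")
  a <- diag(n) * 0
  dimnames(a) <- list(ids, ids)
  g <- affinity_graph(a, k = 1, modality = "fused")  # self-loops only
  splits <- make_splits(labels, n_folds = 3, seed = 2)
  fit <- train_gat(emb, g, labels, splits,
                   gat_config(hidden_dim = 8, heads = 2, epochs = 120,
                              dropout = 0, seed = 4))
  expect_equal(unname(fit$metrics$mean["f1"]), 1.0)
  expect_equal(nrow(fit$metrics$per_fold), 3L)
  expect_equal(nrow(fit$predictions), n)
  # determinism: same seed and folds give identical predictions
  fit2 <- train_gat(emb, g, labels, splits,
                    gat_config(hidden_dim = 8, heads = 2, epochs = 120,
                               dropout = 0, seed = 4))
  expect_identical(fit$predictions, fit2$predictions)
})

test_that("attention rows still sum to one after training on a real fixture", {
  ds <- small_cohort(n = 30, seed = 3, missing_rate = 0)
  x <- standardize_features(ds$omics$mRNA)$values
  g <- suppressWarnings(build_affinity(x, k = 5))
  train <- rep(c(TRUE, TRUE, FALSE), 10)
  fit <- train_gat(latent_embedding(x, "final"), g, ds$labels, train,
                   gat_config(hidden_dim = 8, heads = 2, epochs = 40, seed = 6))
  for (alpha in fit$attention)
    expect_equal(unname(rowSums(alpha)), rep(1, 30), tolerance = 1e-10)
})
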