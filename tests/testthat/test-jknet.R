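# separable two-block graph fixture: strong within-block edges, few across
block_graph <- function(n_per = 10, p = 6, gap = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  cl <- rep(1:2, each = n_per)
  x <- matrix(rnorm(n * p, mean = gap * cl), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  list(features = standardize_features(x),
       graph = suppressWarnings(build_affinity(x, k = 3)),
       labels = factor(cl))
}

test_that("one propagation step equals the normalised-adjacency product", {
  # 3-node path graph, unit weights, W = I
  a <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  g <- affinity_graph(a, k = 1, modality = "CNA")
  h <- matrix(c(1, 0, 2, -1, 1, 0), 3, 2)
  # hand-built Ahat: A+I has degrees (2,3,2)
  deg <- c(2, 3, 2)
  ahat <- (a + diag(3)) / sqrt(outer(deg, deg))
  expect_equal(unname(jk_layer(h, g, diag(2))), unname(pmax(ahat %*% h, 0)),
               tolerance = 1e-12)

  # no edges + identity weights: output is ReLU of the input itself
  eye <- diag(3)
  dimnames(eye) <- dimnames(a)
  g0 <- affinity_graph(eye, k = 1, modality = "CNA")
  hpos <- abs(h)
  expect_equal(unname(jk_layer(hpos, g0, diag(2))), unname(hpos))
})

test_that("disconnected components propagate independently", {
  a <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  g <- affinity_graph(a, k = 1, modality = "CNA")
  h1 <- matrix(c(1, 2, 3, 4), 4, 1)
  h2 <- h1
  h2[3:4] <- c(100, -5)    # perturb only the second component
  W <- matrix(1, 1, 1)
  o1 <- jk_layer(h1, g, W)
  o2 <- jk_layer(h2, g, W)
  expect_equal(o1[1:2, ], o2[1:2, ])
  expect_false(isTRUE(all.equal(o1[3:4, ], o2[3:4, ])))
})

test_that("layer aggregation concatenates, maxes and slices correctly", {
  h0 <- matrix(1:6, 3, 2)
  h1 <- matrix(0, 3, 2)
  h2 <- matrix(-1, 3, 2)
  expect_equal(dim(jk_aggregate(list(h0, h1, h2), "cat")), c(3L, 6L))
  expect_equal(jk_aggregate(list(h0, h0), "max"), h0)   # idempotent
  # max of {h, -h} with h >= 0 is |h|
  h <- matrix(c(-2, 3, 0, -1, 5, -4), 3, 2)
  expect_equal(jk_aggregate(list(h, -h), "max"), abs(h))
  expect_equal(jk_aggregate(list(h0, h2), "last"), h2)
  expect_error(jk_aggregate(list(h0, matrix(0, 3, 3)), "max"), "equal layer widths")
  # cat always keeps layer-0 information even when deeper layers are dead
  agg <- jk_aggregate(list(h0, h1), "cat")
  expect_true(all(agg[, 1:2] == h0))
})

test_that("a separable two-block graph is learned to high training accuracy", {
  fx <- block_graph(n_per = 10, seed = 2)
  train <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 4)
  cfg <- jk_config(n_layers = 2, hidden_dim = 16, epochs = 150, seed = 1)
  emb <- train_jk_branch(fx$features, fx$graph, fx$labels, train, cfg, "toy")
  rep <- attr(emb, "report")
  expect_gte(rep$train_accuracy, 0.95)
  # cat-mode embedding width is (L+1) * hidden
  expect_equal(ncol(emb$values), 3L * 16L)
  # determinism
  emb2 <- train_jk_branch(fx$features, fx$graph, fx$labels, train, cfg, "toy")
  expect_identical(emb$values, emb2$values)
})

test_that("permuted labels yield chance-level held-out accuracy", {
  fx <- block_graph(n_per = 12, seed = 5)
  train <- rep(c(TRUE, TRUE, FALSE), 8)
  accs <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    ylab <- sample(fx$labels)
    cfg <- jk_config(n_layers = 2, hidden_dim = 8, epochs = 80, seed = s)
    emb <- train_jk_branch(fx$features, fx$graph, ylab, train, cfg, "null")
    pred <- attr(emb, "report")$predictions
    mean(pred[!train] == as.integer(ylab)[!train])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("node permutation machinery is exactly equivariant without dropout", {
  fx <- block_graph(n_per = 8, seed = 11)
  train <- rep(c(TRUE, FALSE), 8)
  cfg <- jk_config(n_layers = 2, hidden_dim = 8, epochs = 30, dropout = 0,
                   seed = 9)
  emb <- train_jk_branch(fx$features, fx$graph, fx$labels, train, cfg, "perm")
  set.seed(99)
  perm <- sample(16)
  gp <- affinity_graph(fx$graph$weights[perm, perm], fx$graph$k, "CNA")
  embp <- train_jk_branch(fx$features[perm, ], gp, fx$labels[perm],
                          train[perm], cfg, "perm")
  expect_equal(embp$values[order(perm), ], emb$values,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("branch runners return aligned embeddings per modality and patient", {
  ds <- small_cohort(n = 45, seed = 31, missing_rate = 0)
  x <- lapply(ds$omics, function(m) standardize_features(m)$values)
  graphs <- lapply(ds$omics, function(m)
    suppressWarnings(build_affinity(standardize_features(m), k = 6)))
  train <- rep(c(TRUE, TRUE, FALSE), 15)
  cfg <- jk_config(n_layers = 2, hidden_dim = 8, epochs = 30, seed = 2)
  embs <- run_input1(x, graphs, ds$labels, train, cfg)
  expect_named(embs, names(ds$omics))
  for (e in embs) {
    expect_equal(nrow(e$values), 45L)
    expect_equal(sample_ids(e), ds$sample_ids)
  }
  fused <- snf_fuse(normalize_kernels(graphs, 6), t_max = 10)
  ae <- fit_autoencoder(x, ae_config(latent_dim = 8, hidden_cap = 16,
                                     epochs = 20, seed = 3,
                                     loss_weights = c(.2, .2, .3, .3)))
  pe <- run_input2(ae, fused, ds$labels, train, cfg)
  expect_equal(pe$source, "JK_patient")
  expect_equal(nrow(pe$values), 45L)
})

test_that("single-class training masks are rejected", {
  fx <- block_graph(n_per = 6, seed = 3)
  bad <- fx$labels == 1
  expect_error(train_jk_branch(fx$features, fx$graph, fx$labels, bad,
                               jk_config(epochs = 2)), "single class")
})
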