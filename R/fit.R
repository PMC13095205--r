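# Full pipeline: preprocess -> per-omics affinity graphs -> SNF consensus ->
# multimodal autoencoder -> jumping-knowledge branches (per-omics + patient)
# -> concatenated embedding -> graph attention classifier -> cross-validated
# macro metrics and survival analysis. One global seed fans out to
# deterministic per-stage seeds.

#' Pipeline hyperparameter configuration
#'
#' Houses every tunable of the pipeline with its selected default. The
#' `profile` keyword selects per-dataset branch depths: profile
#' `"coadread"` (a many-subtype colorectal-like cohort) deepens the
#' per-omics branches to 3 layers and the patient branch to 4; every other
#' profile uses 2 and 2.
#'
#' @param knn_k Affinity-graph neighbour count (default 20).
#' @param snf_mu Gaussian-kernel bandwidth multiplier (default 0.5).
#' @param snf_iters SNF diffusion iterations (default 20).
#' @param distance Distance metric (default `"sqeuclidean"`).
#' @param ae_weights Per-modality reconstruction weights (default
#'   0.2/0.2/0.3/0.3 for CNA/MET/mRNA/RPPA).
#' @param ae_latent_dim Autoencoder latent width (default 100).
#' @param ae_hidden_cap Autoencoder hidden-width cap (default 500).
#' @param ae_epochs,ae_lr Autoencoder training epochs and learning rate
#'   (defaults 150, 0.001).
#' @param jk_hidden,jk_epochs,jk_lr,jk_dropout,jk_mode Branch hidden width,
#'   epochs, learning rate, dropout and aggregation mode (defaults 100, 150,
#'   0.001, 0.5, `"cat"`).
#' @param input1_layers,input2_layers Branch depths; `NULL` (default) picks
#'   them from `profile`.
#' @param gat_hidden,gat_heads,gat_alpha,gat_dropout,gat_epochs,gat_lr
#'   Attention-classifier hyperparameters (defaults 100, 2, 0.2, 0.5, 150,
#'   0.001).
#' @param n_folds Cross-validation folds (default 5).
#' @param eval_mode `"cv"` (default) or `"holdout"` (single stratified
#'   75/25 split).
#' @param seed Global integer seed.
#' @param profile Dataset profile name (default `"default"`).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(knn_k = 20, snf_mu = 0.5, snf_iters = 20,
                         distance = "sqeuclidean",
                         ae_weights = c(CNA = 0.2, MET = 0.2, mRNA = 0.3, RPPA = 0.3),
                         ae_latent_dim = 100, ae_hidden_cap = 500,
                         ae_epochs = 150, ae_lr = 0.001,
                         jk_hidden = 100, jk_epochs = 150, jk_lr = 0.001,
                         jk_dropout = 0.5, jk_mode = "cat",
                         input1_layers = NULL, input2_layers = NULL,
                         gat_hidden = 100, gat_heads = 2, gat_alpha = 0.2,
                         gat_dropout = 0.5, gat_epochs = 150, gat_lr = 0.001,
                         n_folds = 5, eval_mode = c("cv", "holdout"),
                         seed = 1, profile = "default") {
  eval_mode <- match.arg(eval_mode)
  deep <- identical(tolower(profile), "coadread")
  if (is.null(input1_layers)) input1_layers <- if (deep) 3L else 2L
  if (is.null(input2_layers)) input2_layers <- if (deep) 4L else 2L
  structure(list(knn_k = as.integer(knn_k), snf_mu = snf_mu,
                 snf_iters = as.integer(snf_iters), distance = distance,
                 ae_weights = ae_weights,
                 ae_latent_dim = as.integer(ae_latent_dim),
                 ae_hidden_cap = as.integer(ae_hidden_cap),
                 ae_epochs = as.integer(ae_epochs), ae_lr = ae_lr,
                 jk_hidden = as.integer(jk_hidden),
                 jk_epochs = as.integer(jk_epochs), jk_lr = jk_lr,
                 jk_dropout = jk_dropout, jk_mode = jk_mode,
                 input1_layers = as.integer(input1_layers),
                 input2_layers = as.integer(input2_layers),
                 gat_hidden = as.integer(gat_hidden),
                 gat_heads = as.integer(gat_heads), gat_alpha = gat_alpha,
                 gat_dropout = gat_dropout,
                 gat_epochs = as.integer(gat_epochs), gat_lr = gat_lr,
                 n_folds = as.integer(n_folds), eval_mode = eval_mode,
                 seed = as.integer(seed), profile = profile),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config>\n")
  cat(sprintf("  graph: k=%d mu=%.2f snf_iters=%d metric=%s\n",
              x$knn_k, x$snf_mu, x$snf_iters, x$distance))
  cat(sprintf("  ae: latent=%d epochs=%d lr=%g weights=(%s)\n",
              x$ae_latent_dim, x$ae_epochs, x$ae_lr,
              paste(x$ae_weights, collapse = ",")))
  cat(sprintf("  jk: hidden=%d mode=%s layers=%d/%d epochs=%d dropout=%.1f\n",
              x$jk_hidden, x$jk_mode, x$input1_layers, x$input2_layers,
              x$jk_epochs, x$jk_dropout))
  cat(sprintf("  gat: hidden=%d heads=%d alpha=%.1f epochs=%d\n",
              x$gat_hidden, x$gat_heads, x$gat_alpha, x$gat_epochs))
  cat(sprintf("  eval: %s (%d folds), seed=%d, profile=%s\n",
              x$eval_mode, x$n_folds, x$seed, x$profile))
  invisible(x)
}

# one fold's model stack: AE -> branches -> concatenated embedding.
# x_raw: named list of preprocessed (unstandardised) feature matrices.
pipeline_fold <- function(x_raw, graphs, fused, labels, train_mask, config,
                          tag, include_patient = TRUE, input1_mode = NULL,
                          input2_mode = NULL) {
  x_std <- lapply(x_raw, function(x)
    standardize_features(x[train_mask, , drop = FALSE], x))
  weights <- config$ae_weights[seq_along(x_std)]
  weights <- weights / sum(weights)
  ae <- fit_autoencoder(
    x_std,
    ae_config(latent_dim = config$ae_latent_dim, loss_weights = weights,
              hidden_cap = config$ae_hidden_cap, epochs = config$ae_epochs,
              learning_rate = config$ae_lr,
              seed = stage_seed(config$seed, paste0("ae_", tag))),
    train_ids = train_mask)
  jk1 <- jk_config(n_layers = config$input1_layers,
                   hidden_dim = config$jk_hidden,
                   mode = if (is.null(input1_mode)) config$jk_mode else input1_mode,
                   dropout = config$jk_dropout,
                   learning_rate = config$jk_lr, epochs = config$jk_epochs,
                   seed = stage_seed(config$seed, paste0("in1_", tag)))
  branches <- run_input1(x_std, graphs, labels, train_mask, jk1)
  if (include_patient) {
    jk2 <- jk_config(n_layers = config$input2_layers,
                     hidden_dim = config$jk_hidden,
                     mode = if (is.null(input2_mode)) config$jk_mode else input2_mode,
                     dropout = config$jk_dropout,
                     learning_rate = config$jk_lr, epochs = config$jk_epochs,
                     seed = stage_seed(config$seed, paste0("in2_", tag)))
    branches$Patients <- run_input2(ae, fused, labels, train_mask, jk2)
  }
  emb <- concat_embeddings(branches)
  params <- c(list(ae = attr(ae, "params")),
              lapply(branches, attr, "params"))
  list(ae = ae, branches = branches, embedding = emb, params = params)
}

gat_config_for <- function(config, tag) {
  gat_config(hidden_dim = config$gat_hidden, heads = config$gat_heads,
             leaky_slope = config$gat_alpha, dropout = config$gat_dropout,
             learning_rate = config$gat_lr, epochs = config$gat_epochs,
             seed = stage_seed(config$seed, paste0("gat_", tag)))
}

#' Fit the full multi-omics graph classification pipeline
#'
#' Preprocesses each modality (missing/zero feature filters + zero
#' imputation), builds per-omics affinity graphs and their SNF consensus
#' once for the whole cohort (transductive: graph structure uses all
#' patients, labels of test patients never enter any loss), then per
#' cross-validation fold trains the autoencoder, the jumping-knowledge
#' branches and the attention classifier on training-fold labels only and
#' predicts the held-out fold. A final all-training-samples fit produces
#' the cohort embedding used for survival analysis and visualisation.
#'
#' @param dataset A [multiomics_dataset()] (missing values allowed; they are
#'   filtered/imputed here).
#' @param config A [train_config()].
#' @param splits Optional [make_splits()] plan; by default derived from
#'   `config` (stratified).
#' @param final_fit Run the final all-sample fit for embeddings/survival
#'   (default `TRUE`).
#' @return An object of class `"jkomics"`: list with `metrics`
#'   (a [metrics_report()]), `predictions` (per test-fold data.frame),
#'   `embedding` (final [latent_embedding()]), `survival` (risk table,
#'   Kaplan-Meier curves, log-rank test, concordance index; `NULL` without
#'   survival data), `network` (per-omics graphs + fused consensus),
#'   `splits`, `config`, `fold_checksums`, `attention`, `timings`.
#' @export
jkomics <- function(dataset, config = train_config(), splits = NULL,
                    final_fit = TRUE) {
  stopifnot(inherits(dataset, "multiomics_dataset"),
            inherits(config, "train_config"))
  t0 <- proc.time()[["elapsed"]]
  omics <- lapply(dataset$omics, filter_and_impute)
  ds <- multiomics_dataset(omics, dataset$labels, dataset$survival)
  labels <- ds$labels
  if (is.null(splits))
    splits <- make_splits(labels, n_folds = config$n_folds,
                          seed = config$seed, stratified = TRUE,
                          mode = config$eval_mode)
  network <- build_patient_network(ds, k = config$knn_k, mu = config$snf_mu,
                                   t_max = config$snf_iters,
                                   metric = config$distance)
  # the SNF consensus is dense; the attention classifier needs an actual
  # neighbourhood, so it runs on the top-k consensus neighbours
  network$fused_knn <- suppressWarnings(
    knn_sparsify(network$fused$weights,
                 k = min(config$knn_k, length(labels) - 1),
                 modality = "fused"))
  t_graph <- proc.time()[["elapsed"]]
  x_raw <- lapply(ds$omics, function(m) m$values)
  per_fold <- list()
  rows <- list()
  checksums <- numeric(0)
  for (f in splits$test_folds) {
    test <- splits$fold_of == f
    stack <- pipeline_fold(x_raw, network$graphs, network$fused, labels,
                           !test, config, tag = paste0("f", f))
    fit <- gat_fit(stack$embedding, network$fused_knn, labels, !test,
                   gat_config_for(config, paste0("f", f)),
                   stage = paste0("gat_f", f))
    per_fold[[length(per_fold) + 1]] <-
      macro_metrics(labels[test], fit$predictions[test],
                    levels = levels(labels))
    probs <- fit$probabilities[test, , drop = FALSE]
    colnames(probs) <- paste0("p_", levels(labels))
    rows[[length(rows) + 1]] <-
      data.frame(sample_id = ds$sample_ids[test], fold = f,
                 true = labels[test], predicted = fit$predictions[test],
                 probs, row.names = NULL, check.names = FALSE)
    checksums[paste0("fold", f)] <-
      param_checksum(c(stack$params, list(gat = fit$params)))
  }
  t_cv <- proc.time()[["elapsed"]]
  embedding <- NULL
  surv_eval <- NULL
  attention <- NULL
  if (final_fit) {
    all_train <- rep(TRUE, length(labels))
    stack <- pipeline_fold(x_raw, network$graphs, network$fused, labels,
                           all_train, config, tag = "final")
    fit <- gat_fit(stack$embedding, network$fused_knn, labels, all_train,
                   gat_config_for(config, "final"), stage = "gat_final")
    embedding <- stack$embedding
    attention <- fit$attention
    if (!is.null(ds$survival) && sum(ds$survival$event, na.rm = TRUE) >= 2)
      surv_eval <- evaluate_survival(embedding, ds$survival$time,
                                     ds$survival$event, seed = config$seed)
  }
  t_end <- proc.time()[["elapsed"]]
  structure(list(
    metrics = metrics_report(per_fold, nlevels(labels)),
    predictions = do.call(rbind, rows),
    embedding = embedding,
    survival = surv_eval,
    network = network,
    splits = splits,
    config = config,
    labels = labels,
    n_samples = length(labels),
    fold_checksums = checksums,
    attention = attention,
    timings = c(graphs = t_graph - t0, cv = t_cv - t_graph,
                final = t_end - t_cv)),
    class = "jkomics")
}

#' @export
print.jkomics <- function(x, ...) {
  cat(sprintf("<jkomics> %d samples, %d classes, %s over %d folds\n",
              x$n_samples, x$metrics$n_classes, x$splits$mode,
              nrow(x$metrics$per_fold)))
  print(x$metrics)
  if (!is.null(x$survival))
    cat(sprintf("  survival: log-rank chi2 = %.2f (p = %.3g), C-index = %.3f\n",
                x$survival$logrank$chi2, x$survival$logrank$p_value,
                x$survival$c_index))
  invisible(x)
}

#' @export
summary.jkomics <- function(object, ...) {
  print(object)
  cat("\nPer-fold macro metrics (%):\n")
  print(round(100 * object$metrics$per_fold, 2))
  conv <- attr(object$network$fused, "convergence")
  cat(sprintf("\nSNF max-abs change: %.2e (iter 1) -> %.2e (iter %d)\n",
              conv[1], conv[length(conv)], length(conv)))
  invisible(object)
}

#' @export
predict.jkomics <- function(object, ...) object$predictions

#' Plot the fitted embedding in principal-component space
#'
#' @param x A fitted `"jkomics"` object (with `final_fit = TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @return The PCA coordinate table, invisibly.
#' @export
plot.jkomics <- function(x, ...) {
  if (is.null(x$embedding)) stop("no final embedding; refit with final_fit = TRUE")
  coords <- export_embeddings_pca(x$embedding, x$labels)
  cls <- as.integer(factor(coords$label))
  graphics::plot(coords$PC1, coords$PC2, col = cls, pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = "Embedding, first two principal components", ...)
  graphics::legend("topright", legend = levels(factor(coords$label)),
                   col = seq_len(max(cls)), pch = 19, cex = 0.8)
  invisible(coords)
}

#' Project an embedding onto its first two principal components
#'
#' @param embedding A [latent_embedding()] or numeric matrix (`n >= 3`).
#' @param labels Optional per-sample labels to attach.
#' @return `data.frame` with `sample_id`, `PC1`, `PC2` and `label`;
#'   attribute `var_explained` gives each component's variance share.
#' @export
export_embeddings_pca <- function(embedding, labels = NULL) {
  v <- if (inherits(embedding, "latent_embedding")) embedding$values
       else embedding
  if (nrow(v) < 3) stop("need at least 3 samples")
  if (all(apply(v, 2, stats::sd) == 0)) stop("constant embedding")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = 2)
  out <- data.frame(sample_id = rownames(v),
                    PC1 = pc$x[, 1],
                    PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0,
                    row.names = NULL)
  out$label <- if (is.null(labels)) NA else as.character(labels)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[seq_len(min(2, length(ve)))]
  out
}

#' Ablation harnesses
#'
#' Re-runs the pipeline under controlled modifications and tabulates
#' cross-validated macro metrics:
#' \describe{
#'   \item{`exclude_one_omics`}{drops each input in turn - every omics
#'     modality and the patient-level branch - plus the full model
#'     (columns: each excluded input, then `All`).}
#'   \item{`jk_vs_gcn_input1` / `jk_vs_gcn_input2`}{replaces the named
#'     branch's jumping-knowledge aggregation with a final-layer-only GCN of
#'     equal depth.}
#'   \item{`single_branch`}{classifies from each branch's embedding alone.}
#' }
#'
#' @param dataset A [multiomics_dataset()].
#' @param config A [train_config()].
#' @param which One of `"exclude_one_omics"`, `"jk_vs_gcn_input1"`,
#'   `"jk_vs_gcn_input2"`, `"single_branch"`.
#' @return `data.frame` of macro metrics (mean and sd, %) per variant.
#' @export
run_ablation <- function(dataset, config = train_config(),
                         which = c("exclude_one_omics", "jk_vs_gcn_input1",
                                   "jk_vs_gcn_input2", "single_branch")) {
  which <- match.arg(which)
  row_of <- function(fit, name) {
    data.frame(variant = name,
               precision = 100 * fit$metrics$mean["precision"],
               recall = 100 * fit$metrics$mean["recall"],
               f1 = 100 * fit$metrics$mean["f1"],
               precision_sd = 100 * fit$metrics$sd["precision"],
               recall_sd = 100 * fit$metrics$sd["recall"],
               f1_sd = 100 * fit$metrics$sd["f1"],
               row.names = NULL)
  }
  if (which == "exclude_one_omics") {
    mods <- names(dataset$omics)
    out <- list()
    for (m in mods) {
      sub <- multiomics_dataset(dataset$omics[setdiff(mods, m)],
                                dataset$labels, dataset$survival)
      cfg <- config
      cfg$ae_weights <- config$ae_weights[setdiff(mods, m)]
      out[[m]] <- row_of(jkomics(sub, cfg, final_fit = FALSE), m)
    }
    out$Patients <- row_of(
      jkomics_variant(dataset, config, include_patient = FALSE), "Patients")
    out$All <- row_of(jkomics(dataset, config, final_fit = FALSE), "All")
    return(do.call(rbind, out))
  }
  if (which %in% c("jk_vs_gcn_input1", "jk_vs_gcn_input2")) {
    slot <- if (which == "jk_vs_gcn_input1") "input1_mode" else "input2_mode"
    jk <- jkomics_variant(dataset, config)
    args <- list(dataset = dataset, config = config)
    args[[slot]] <- "last"
    gcn <- do.call(jkomics_variant, args)
    return(rbind(row_of(jk, "JK"), row_of(gcn, "GCN")))
  }
  # single_branch: classify from each branch embedding alone, per fold
  omics <- lapply(dataset$omics, filter_and_impute)
  ds <- multiomics_dataset(omics, dataset$labels, dataset$survival)
  labels <- ds$labels
  splits <- make_splits(labels, n_folds = config$n_folds, seed = config$seed,
                        stratified = TRUE, mode = config$eval_mode)
  network <- build_patient_network(ds, k = config$knn_k, mu = config$snf_mu,
                                   t_max = config$snf_iters,
                                   metric = config$distance)
  # the SNF consensus is dense; the attention classifier needs an actual
  # neighbourhood, so it runs on the top-k consensus neighbours
  network$fused_knn <- suppressWarnings(
    knn_sparsify(network$fused$weights,
                 k = min(config$knn_k, length(labels) - 1),
                 modality = "fused"))
  x_raw <- lapply(ds$omics, function(m) m$values)
  branch_names <- c(names(ds$omics), "Patients")
  per_branch <- stats::setNames(
    replicate(length(branch_names), list(), simplify = FALSE), branch_names)
  for (f in splits$test_folds) {
    test <- splits$fold_of == f
    stack <- pipeline_fold(x_raw, network$graphs, network$fused, labels,
                           !test, config, tag = paste0("f", f))
    for (b in branch_names) {
      fit <- gat_fit(stack$branches[[b]], network$fused_knn, labels, !test,
                     gat_config_for(config, paste0(b, "_f", f)),
                     stage = paste0("gat_", b, "_f", f))
      per_branch[[b]][[length(per_branch[[b]]) + 1]] <-
        macro_metrics(labels[test], fit$predictions[test],
                      levels = levels(labels))
    }
  }
  do.call(rbind, lapply(branch_names, function(b) {
    rep <- metrics_report(per_branch[[b]], nlevels(labels))
    data.frame(variant = b,
               precision = 100 * rep$mean["precision"],
               recall = 100 * rep$mean["recall"],
               f1 = 100 * rep$mean["f1"],
               precision_sd = 100 * rep$sd["precision"],
               recall_sd = 100 * rep$sd["recall"],
               f1_sd = 100 * rep$sd["f1"],
               row.names = NULL)
  }))
}

# pipeline run with branch-level modifications (used by the ablations)
jkomics_variant <- function(dataset, config, include_patient = TRUE,
                            input1_mode = NULL, input2_mode = NULL) {
  omics <- lapply(dataset$omics, filter_and_impute)
  ds <- multiomics_dataset(omics, dataset$labels, dataset$survival)
  labels <- ds$labels
  splits <- make_splits(labels, n_folds = config$n_folds, seed = config$seed,
                        stratified = TRUE, mode = config$eval_mode)
  network <- build_patient_network(ds, k = config$knn_k, mu = config$snf_mu,
                                   t_max = config$snf_iters,
                                   metric = config$distance)
  # the SNF consensus is dense; the attention classifier needs an actual
  # neighbourhood, so it runs on the top-k consensus neighbours
  network$fused_knn <- suppressWarnings(
    knn_sparsify(network$fused$weights,
                 k = min(config$knn_k, length(labels) - 1),
                 modality = "fused"))
  x_raw <- lapply(ds$omics, function(m) m$values)
  per_fold <- list()
  for (f in splits$test_folds) {
    test <- splits$fold_of == f
    stack <- pipeline_fold(x_raw, network$graphs, network$fused, labels,
                           !test, config, tag = paste0("f", f),
                           include_patient = include_patient,
                           input1_mode = input1_mode,
                           input2_mode = input2_mode)
    fit <- gat_fit(stack$embedding, network$fused_knn, labels, !test,
                   gat_config_for(config, paste0("f", f)),
                   stage = paste0("gat_f", f))
    per_fold[[length(per_fold) + 1]] <-
      macro_metrics(labels[test], fit$predictions[test],
                    levels = levels(labels))
  }
  list(metrics = metrics_report(per_fold, nlevels(labels)), splits = splits)
}

#' Write a fitted pipeline's outputs to a results directory
#'
#' Writes `metrics.json` (per-fold and mean/sd macro metrics), per-fold
#' `predictions.csv`, the final embedding, PCA coordinates, Kaplan-Meier
#' curve data and the survival table as delimited text.
#'
#' @param fit A fitted `"jkomics"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- list(
    per_fold = apply(fit$metrics$per_fold, 1, as.list),
    mean = as.list(fit$metrics$mean),
    sd = as.list(fit$metrics$sd),
    n_classes = fit$metrics$n_classes,
    seed = fit$config$seed)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(fit$predictions, file.path(dir, "predictions.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$embedding)) {
    emb <- cbind(sample_id = rownames(fit$embedding$values),
                 as.data.frame(fit$embedding$values))
    utils::write.table(emb, file.path(dir, "embedding.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pca <- export_embeddings_pca(fit$embedding, fit$labels)
    utils::write.table(pca, file.path(dir, "pca.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$survival)) {
    utils::write.table(fit$survival$km, file.path(dir, "km_curves.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$survival$table, file.path(dir, "risk_groups.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
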