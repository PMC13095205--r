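# Evaluation: macro-averaged classification metrics across folds, and
# survival analysis of embedding-derived risk scores (Kaplan-Meier curves,
# log-rank test, concordance index). The survival statistics are delegated
# to the survival package; the concordance index is computed in-repo to
# match the exact comparable-pair definition used here.

#' Macro-averaged precision, recall and F1
#'
#' Unweighted means of the per-class metrics, insensitive to class
#' frequency. A class never predicted contributes precision 0; a class with
#' zero precision and recall contributes F1 0.
#'
#' @param true Factor (or vector) of true labels.
#' @param predicted Factor (or vector) of predicted labels, same length.
#' @param levels Optional class levels; defaults to the union of both.
#' @return Named numeric vector `c(precision, recall, f1)`, each in
#'   `[0, 1]`. Attribute `confusion` holds the confusion matrix.
#' @export
macro_metrics <- function(true, predicted, levels = NULL) {
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have equal length")
  if (is.null(levels))
    levels <- union(levels(as.factor(true)), levels(as.factor(predicted)))
  true <- factor(true, levels = levels)
  predicted <- factor(predicted, levels = levels)
  cm <- table(true = true, predicted = predicted)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  out <- c(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
  attr(out, "confusion") <- cm
  out
}

#' Bundle per-fold macro metrics into a report
#'
#' @param per_fold List of [macro_metrics()] results, one per fold.
#' @param n_classes Number of classes.
#' @return An object of class `"metrics_report"` with per-fold values and
#'   mean/sd per metric.
#' @export
metrics_report <- function(per_fold, n_classes) {
  tab <- do.call(rbind, lapply(per_fold, as.numeric))
  colnames(tab) <- c("precision", "recall", "f1")
  structure(list(per_fold = tab,
                 mean = colMeans(tab),
                 sd = apply(tab, 2, stats::sd),
                 n_classes = as.integer(n_classes),
                 confusion = lapply(per_fold, attr, "confusion")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds, %d classes (macro, %%)\n",
              nrow(x$per_fold), x$n_classes))
  for (m in colnames(x$per_fold))
    cat(sprintf("  %-9s %6.2f +/- %.2f\n", m,
                100 * x$mean[m], 100 * if (is.na(x$sd[m])) 0 else x$sd[m]))
  invisible(x)
}

#' Kaplan-Meier survival curves per risk group
#'
#' Product-limit estimates `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times of each group; censored patients leave the risk set
#' after their time.
#'
#' @param table A survival table: `data.frame` with columns `time`
#'   (positive), `event` (0/1) and `group`.
#' @return `data.frame` with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (one row per distinct time per group).
#' @export
kaplan_meier <- function(table) {
  stopifnot(all(c("time", "event", "group") %in% names(table)))
  if (any(table$time <= 0)) stop("survival times must be positive")
  out <- lapply(split(table, table$group), function(d) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = d$group[1], time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' Tests equality of the two groups' survival functions:
#' `chi2 = (O1 - E1)^2 / V1` with `O1` the observed events in the high-risk
#' group, `E1` the events expected under the null and `V1` the hypergeometric
#' variance summed over event times; p from a chi-square with 1 df.
#'
#' @param table Survival table with columns `time`, `event`, `group`
#'   (exactly two non-empty groups).
#' @return List with `chi2`, `p_value`, `observed` and `expected` (per
#'   group).
#' @export
logrank_test <- function(table) {
  stopifnot(all(c("time", "event", "group") %in% names(table)))
  g <- factor(table$group)
  if (nlevels(g) != 2) stop("exactly two non-empty groups required")
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = table)
  chi2 <- as.numeric(fit$chisq)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = as.numeric(fit$obs), expected = as.numeric(fit$exp))
}

#' Concordance index of risk scores against survival
#'
#' A pair `(i, j)` is comparable when `t_i < t_j` and patient `i` had an
#' event; it is concordant when `risk_i > risk_j`, and risk ties count 0.5.
#' Returns concordant pairs / comparable pairs.
#'
#' @param risk_scores Numeric risk scores (higher = worse prognosis).
#' @param times Survival times.
#' @param events Event indicators (0/1).
#' @return The concordance index in `[0, 1]`.
#' @export
concordance_index <- function(risk_scores, times, events) {
  stopifnot(length(risk_scores) == length(times),
            length(times) == length(events))
  comparable <- outer(times, times, "<") & (events == 1)
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs")
  rdiff <- outer(risk_scores, risk_scores, "-")
  score <- sum(comparable & rdiff > 0) + 0.5 * sum(comparable & rdiff == 0)
  score / n_comp
}

#' Derive risk scores and median-split risk groups from an embedding
#'
#' Fits a ridge-penalised Cox proportional-hazards head (glmnet,
#' `alpha = 0`) on the embedding; the linear predictor is the risk score.
#' Patients are split at the median score: scores above the median form the
#' high-risk group, scores at or below it the low-risk group. Alternatively
#' a precomputed score vector (e.g. a class probability) may be supplied via
#' `scores`.
#'
#' @param embedding A [latent_embedding()] (or numeric matrix), rows
#'   aligned with `times`/`events`. Ignored when `scores` is given.
#' @param times Survival times (months); `NA` rows are dropped.
#' @param events Event indicators (0/1).
#' @param seed Integer seed (drives the deterministic cross-validation
#'   folds that select the ridge penalty).
#' @param scores Optional precomputed risk scores.
#' @return A survival table: `data.frame` with `sample_id`, `time`,
#'   `event`, `risk_score`, `group` (`"high"`/`"low"`).
#' @export
assign_risk_groups <- function(embedding, times, events, seed = 1,
                               scores = NULL) {
  x <- if (inherits(embedding, "latent_embedding")) embedding$values
       else embedding
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_along(times))
  keep <- !is.na(times) & !is.na(events) & times > 0
  if (sum(keep, na.rm = TRUE) < 3) stop("too few patients with survival data")
  x <- x[keep, , drop = FALSE]
  times <- times[keep]
  events <- events[keep]
  ids <- ids[keep]
  if (is.null(scores)) {
    if (sum(events) < 2) stop("need at least two events to fit the risk head")
    # prevalidated linear predictors: the penalty is chosen by internal
    # cross-validation, then each patient's score comes from a model fitted
    # without that patient's fold, so in-sample optimism cannot inflate the
    # downstream log-rank test or concordance index
    set.seed(stage_seed(seed, "risk_head"))
    foldid <- sample(rep_len(1:5, length(times)))
    y <- survival::Surv(times, events)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 0, foldid = foldid)
    lam <- cv$lambda.min
    scores <- numeric(length(times))
    for (f in unique(foldid)) {
      hold <- foldid == f
      fit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                            family = "cox", alpha = 0, lambda = cv$lambda)
      scores[hold] <- as.numeric(
        predict(fit, newx = x[hold, , drop = FALSE], s = lam))
    }
  } else {
    scores <- scores[keep]
  }
  if (stats::sd(scores) == 0)
    stop("risk scores are constant; inspect the embedding or model")
  med <- stats::median(scores)
  data.frame(sample_id = ids, time = times, event = events,
             risk_score = scores,
             group = ifelse(scores > med, "high", "low"))
}

#' Full survival evaluation of an embedding
#'
#' Runs [assign_risk_groups()], [kaplan_meier()], [logrank_test()] and
#' [concordance_index()] in one call.
#'
#' @inheritParams assign_risk_groups
#' @return List with `table` (the survival table), `km` (Kaplan-Meier
#'   curves), `logrank` (`chi2`, `p_value`), `c_index`.
#' @export
evaluate_survival <- function(embedding, times, events, seed = 1,
                              scores = NULL) {
  tab <- assign_risk_groups(embedding, times, events, seed, scores)
  list(table = tab,
       km = kaplan_meier(tab),
       logrank = logrank_test(tab),
       c_index = concordance_index(tab$risk_score, tab$time, tab$event))
}
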