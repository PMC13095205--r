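# Shared numerical machinery for the neural stages: deterministic per-stage
# seeds, Glorot initialisation, Adam, activations and loss primitives.
# Everything is dense base-R matrix algebra; cohorts are a few hundred
# patients, so full-batch training with BLAS matmuls is the fast path.

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage draws its randomness from a seed deterministically
#' derived from the run's global seed and the stage name, so any stage can be
#' re-run in isolation with identical results.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"ae_fold1"`.
#' @return An integer in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

elu <- function(x) ifelse(x > 0, x, expm1(x))

elu_grad <- function(y) ifelse(y > 0, 1, y + 1)  # in terms of the output

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(labels, n_classes) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

# mean cross-entropy over masked rows; probs already softmaxed
masked_cross_entropy <- function(probs, y_onehot, mask) {
  p <- rowSums(probs * y_onehot)[mask]
  -mean(log(pmax(p, 1e-12)))
}

# inverted dropout mask (scales kept units by 1/(1-p)); p = 0 gives all ones
dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix(rbinom(n * m, 1, 1 - p) / (1 - p), n, m)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flat checksum of a (possibly nested) list of numeric arrays; used by the
# leakage canary to assert that trained parameters are unchanged
param_checksum <- function(params) {
  vals <- unlist(params, use.names = FALSE)
  sum(abs(vals)) + sum(vals * seq_along(vals) %% 97)
}

stop_if_nonfinite <- function(x, what, epoch = NULL) {
  if (any(!is.finite(x)))
    stop(sprintf("non-finite %s%s", what,
                 if (is.null(epoch)) "" else sprintf(" at epoch %d", epoch)))
  invisible(x)
}
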