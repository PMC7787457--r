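# Training objectives.
#
# HF hospitalization labels are heavily skewed toward negatives (a patient
# has a handful of events across decades of 6-month steps), so the default
# objective is the alpha-weighted focal loss, which down-weights
# well-classified examples by the modulating factor (1 - p)^beta (positives)
# or p^beta (negatives) and re-balances the classes with alpha. At beta = 0
# it reduces exactly to the alpha-weighted cross-entropy.

#' Loss configuration
#'
#' @param kind `"focal"` or `"cross_entropy"`.
#' @param alpha Class-balance weight on positives, in (0, 1); default 0.25.
#' @param beta Focusing exponent, >= 0; default 2.
#' @param reduction `"sum"` over all elements or `"mean"`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(kind = c("focal", "cross_entropy"),
                        alpha = 0.25, beta = 2,
                        reduction = c("sum", "mean")) {
  kind <- match.arg(kind)
  reduction <- match.arg(reduction)
  if (alpha <= 0 || alpha >= 1) {
    stop_hftraj("alpha must lie strictly in (0, 1)", "contract_error")
  }
  if (beta < 0) stop_hftraj("beta must be >= 0", "contract_error")
  structure(list(kind = kind, alpha = alpha, beta = beta,
                 reduction = reduction),
            class = "loss_config")
}

reduce_loss <- function(x, reduction) {
  switch(reduction, sum = sum(x), mean = mean(x))
}

#' Binary cross-entropy loss
#'
#' `sum(-y * log(p) - (1 - y) * log(1 - p))` over all elements, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` before the logarithms so the
#' loss is always finite.
#'
#' @param y Binary labels (vector or matrix).
#' @param yhat Predicted probabilities, same shape.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @return A non-negative scalar.
#' @export
cross_entropy <- function(y, yhat, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (length(y) != length(yhat)) {
    stop_hftraj("labels and predictions have different lengths", "contract_error")
  }
  p <- clamp_prob(yhat)
  reduce_loss(-y * log(p) - (1 - y) * log(1 - p), reduction)
}

#' Alpha-weighted focal loss
#'
#' `sum(-alpha * (1 - p)^beta * y * log(p)
#'      - (1 - alpha) * p^beta * (1 - y) * log(1 - p))`.
#' Equals the alpha-weighted cross-entropy exactly when `beta = 0`.
#'
#' @inheritParams cross_entropy
#' @param alpha,beta See [loss_config()].
#' @return A non-negative scalar.
#' @export
focal_loss <- function(y, yhat, alpha = 0.25, beta = 2,
                       reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (length(y) != length(yhat)) {
    stop_hftraj("labels and predictions have different lengths", "contract_error")
  }
  p <- clamp_prob(yhat)
  reduce_loss(
    -alpha * (1 - p)^beta * y * log(p) -
      (1 - alpha) * p^beta * (1 - y) * log(1 - p),
    reduction
  )
}

#' Multi-task loss over HF and acute co-morbidity channels
#'
#' The multi-output objective of the co-morbidity-augmented model: the
#' configured per-element loss (focal or cross-entropy) applied to every
#' channel of the multi-label target with equal weight, so the total
#' decomposes exactly as HF loss + co-morbidity loss.
#'
#' @param targets N x 4 matrix of labels (column 1: HF; columns 2..4: acute
#'   co-morbidities).
#' @param outputs N x 4 matrix of predicted probabilities.
#' @param config A [loss_config()].
#' @return A list with `total`, `hf` and `cm` loss components.
#' @export
multi_task_loss <- function(targets, outputs, config = loss_config()) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  if (!all(dim(targets) == dim(outputs))) {
    stop_hftraj("targets and outputs have different channel layouts",
                "contract_error")
  }
  per <- function(y, p) {
    if (config$kind == "focal") {
      focal_loss(y, p, config$alpha, config$beta, config$reduction)
    } else {
      cross_entropy(y, p, config$reduction)
    }
  }
  hf <- per(targets[, 1], outputs[, 1])
  cm <- per(targets[, -1, drop = FALSE], outputs[, -1, drop = FALSE])
  if (config$reduction == "mean") {
    # keep exact additivity total = hf + cm under the sum convention;
    # for the mean convention weight the components by element counts
    n_hf <- length(targets[, 1]); n_cm <- length(targets[, -1])
    total <- (hf * n_hf + cm * n_cm) / (n_hf + n_cm)
  } else {
    total <- hf + cm
  }
  list(total = total, hf = hf, cm = cm)
}

# gradient of the per-element loss w.r.t. the logit (through the sigmoid),
# computed at the clamped probability
loss_grad_logit <- function(y, p, config) {
  p <- clamp_prob(p)
  if (config$kind == "cross_entropy") {
    return(p - y)
  }
  a <- config$alpha; b <- config$beta
  # d/dp of the focal loss, then times sigmoid'(logit) = p (1 - p)
  dpos <- -a * (-b * (1 - p)^(b - 1) * log(p) + (1 - p)^b / p)
  dneg <- -(1 - a) * (b * p^(b - 1) * log(1 - p) - p^b / (1 - p))
  (y * dpos + (1 - y) * dneg) * p * (1 - p)
}

# gradient of the per-element loss w.r.t. the probability itself (used where
# the probability feeds later layers, as in the CM branch of dhtm_c)
loss_grad_prob <- function(y, p, config) {
  p <- clamp_prob(p)
  if (config$kind == "cross_entropy") {
    return(-y / p + (1 - y) / (1 - p))
  }
  a <- config$alpha; b <- config$beta
  dpos <- -a * (-b * (1 - p)^(b - 1) * log(p) + (1 - p)^b / p)
  dneg <- -(1 - a) * (b * p^(b - 1) * log(1 - p) - p^b / (1 - p))
  y * dpos + (1 - y) * dneg
}
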