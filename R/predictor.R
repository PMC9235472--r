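# Multi-label predictor: adapter network, dot-product scoring,
# binary-cross-entropy loss, decision rule.

#' Map a compound embedding into the pathway embedding space
#'
#' A three-layer dense network (input, ReLU hidden, linear output) aligning
#' the compound embedding space with the pathway embedding space so that
#' dot products between the two are meaningful.
#'
#' @param z Compound embedding vector (length 2t).
#' @param params Adapter parameters: \code{W1}, \code{b1}, \code{W2},
#'   \code{b2}.
#' @return Numeric vector of length B.
#' @export
adapt <- function(z, params) {
  if (length(z) != nrow(params$W1))
    stop(sprintf("adapter expects input of length %d, got %d",
                 nrow(params$W1), length(z)))
  u <- relu(drop(z %*% params$W1) + params$b1)
  drop(u %*% params$W2) + params$b2
}

#' Score pathway membership by embedding proximity
#'
#' The logit for pathway i is the plain inner product of the i-th pathway
#' embedding with the adapted compound embedding; no bias term.
#'
#' @param O C x B pathway embedding matrix.
#' @param z_adapted Adapted compound embedding of length B.
#' @return Numeric logit vector of length C.
#' @export
score_pathways <- function(O, z_adapted) {
  stopifnot(ncol(O) == length(z_adapted))
  drop(O %*% z_adapted)
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Multi-label classification loss
#'
#' Mean per-label binary cross-entropy with logits: each label contributes
#' \code{y * softplus(-yhat) + (1 - y) * softplus(yhat)}, averaged over the
#' C labels. Stable for |logit| up to at least 1e4 via the softplus guard.
#'
#' @param yhat Logit vector of length C.
#' @param y Binary truth vector of length C.
#' @return Scalar loss.
#' @export
multilabel_loss <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  mean(y * softplus(-yhat) + (1 - y) * softplus(yhat))
}

#' Gradient of the multi-label loss with respect to the logits
#'
#' Equals \code{(sigmoid(yhat) - y) / C} per label.
#'
#' @inheritParams multilabel_loss
#' @return Gradient vector of length C.
#' @export
multilabel_loss_grad <- function(yhat, y) {
  (stats::plogis(yhat) - y) / length(y)
}

#' Threshold logits into binary pathway calls
#'
#' A pathway is called positive when the sigmoid of its logit reaches the
#' probability threshold. Ranking metrics never use this rule.
#'
#' @param yhat Logit vector (or n x C matrix).
#' @param threshold Probability threshold in (0, 1); default 0.5.
#' @return Binary vector (or matrix) of the same shape.
#' @export
decide <- function(yhat, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (stats::plogis(yhat) >= threshold) * 1
}
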