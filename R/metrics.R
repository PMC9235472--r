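# The eight multi-label evaluation metrics. Accuracy/precision/recall/F1
# are micro label-based over all (sample, label) cells; HL/RL/Coverage/OE
# follow the standard multi-label definitions. Ties in rankings break by
# ascending label index.

as_label_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(dim(x)) || length(dim(x)) < 2L) m <- matrix(x, nrow = 1)
  m
}

#' Hamming loss
#'
#' Fraction of (sample, label) cells where decision and truth disagree.
#'
#' @param Y n x C binary truth matrix.
#' @param D n x C binary decision matrix.
#' @return Scalar in [0, 1].
#' @export
hamming_loss <- function(Y, D) {
  Y <- as_label_matrix(Y); D <- as_label_matrix(D)
  stopifnot(all(dim(Y) == dim(D)))
  mean(Y != D)
}

#' Micro label-based accuracy, precision, recall and F1
#'
#' Confusion counts are pooled over every (sample, label) cell:
#' accuracy = (TP + TN) / (n C), precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 their harmonic mean. Undefined ratios
#' (zero denominator) return 0 with a warning. Micro accuracy is exactly
#' 1 minus the Hamming loss.
#'
#' @param Y n x C binary truth matrix.
#' @param D n x C binary decision matrix.
#' @return Named list: \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
prf_accuracy <- function(Y, D) {
  Y <- as_label_matrix(Y); D <- as_label_matrix(D)
  stopifnot(all(dim(Y) == dim(D)))
  tp <- sum(Y == 1 & D == 1); tn <- sum(Y == 0 & D == 0)
  fp <- sum(Y == 0 & D == 1); fn <- sum(Y == 1 & D == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator); using 0"); 0 }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(Y), precision = precision,
       recall = recall, f1 = f1)
}

# Rank of each label by descending score; ties broken by ascending index.
score_ranks <- function(s) rank(-s, ties.method = "first")

#' Ranking loss
#'
#' Per sample, the fraction of (true, false) label pairs where the true
#' label scores no higher than the false one, averaged over samples that
#' have at least one such pair.
#'
#' @param Y n x C binary truth matrix.
#' @param S n x C score matrix.
#' @return Scalar in [0, 1].
#' @export
ranking_loss <- function(Y, S) {
  Y <- as_label_matrix(Y); S <- as_label_matrix(S)
  stopifnot(all(dim(Y) == dim(S)))
  per <- vapply(seq_len(nrow(Y)), function(i) {
    pos <- which(Y[i, ] == 1); neg <- which(Y[i, ] == 0)
    if (!length(pos) || !length(neg)) return(NA_real_)
    bad <- sum(outer(S[i, pos], S[i, neg], "<="))
    bad / (length(pos) * length(neg))
  }, numeric(1))
  if (all(is.na(per))) return(0)
  mean(per, na.rm = TRUE)
}

#' Coverage
#'
#' Per sample, how far down the score-ranked label list one must go to
#' include every true label: the rank of the worst-ranked true label,
#' averaged over samples. Reported 1-based by default; \code{zero_based}
#' subtracts one.
#'
#' @param Y n x C binary truth matrix.
#' @param S n x C score matrix.
#' @param zero_based Use the 0-based convention.
#' @return Scalar in [1, C] (or [0, C - 1]).
#' @export
coverage <- function(Y, S, zero_based = FALSE) {
  Y <- as_label_matrix(Y); S <- as_label_matrix(S)
  stopifnot(all(dim(Y) == dim(S)))
  per <- vapply(seq_len(nrow(Y)), function(i) {
    r <- score_ranks(S[i, ])
    max(r[Y[i, ] == 1])
  }, numeric(1))
  mean(per) - if (zero_based) 1 else 0
}

#' One-error
#'
#' Fraction of samples whose top-scored label (ties to the lowest index) is
#' not a true label.
#'
#' @param Y n x C binary truth matrix.
#' @param S n x C score matrix.
#' @return Scalar in [0, 1].
#' @export
one_error <- function(Y, S) {
  Y <- as_label_matrix(Y); S <- as_label_matrix(S)
  stopifnot(all(dim(Y) == dim(S)))
  mean(vapply(seq_len(nrow(Y)), function(i) {
    as.numeric(Y[i, which.max(S[i, ])] != 1)
  }, numeric(1)))
}

#' Compute all eight multi-label metrics
#'
#' @param Y n x C binary truth matrix.
#' @param S n x C score matrix (logits or probabilities; ranking metrics
#'   are invariant to strictly monotone transforms).
#' @param D n x C binary decision matrix; by default thresholded from S at
#'   probability 0.5 (treating S as logits).
#' @param zero_based_coverage Use the 0-based coverage convention.
#' @return Named list with accuracy, precision, recall, f1, hamming_loss,
#'   ranking_loss, coverage, one_error.
#' @export
multilabel_metrics <- function(Y, S, D = NULL, zero_based_coverage = FALSE) {
  if (is.null(D)) D <- decide(S)
  c(prf_accuracy(Y, D),
    list(hamming_loss = hamming_loss(Y, D),
         ranking_loss = ranking_loss(Y, S),
         coverage = coverage(Y, S, zero_based = zero_based_coverage),
         one_error = one_error(Y, S)))
}
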