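## Scoring of an estimated precision matrix against the generating one.

#' Stein loss between two precision matrices
#'
#' \eqn{\delta(K, \hat K) = \mathrm{tr}(K \hat K^{-1}) -
#' \log|K \hat K^{-1}| - m}; non-negative, zero iff the matrices are equal,
#' and invariant to a common congruence transform.
#'
#' @param K_true,K_hat m x m symmetric positive-definite matrices.
#' @return non-negative scalar.
#' @export
stein_loss <- function(K_true, K_hat) {
  m <- nrow(K_true)
  if (!all(dim(K_hat) == dim(K_true))) stop("shape mismatch")
  Rt <- tryCatch(chol(K_true), error = function(e)
    stop("'K_true' is not positive definite", call. = FALSE))
  Rh <- tryCatch(chol(K_hat), error = function(e)
    stop("'K_hat' is not positive definite", call. = FALSE))
  M <- K_true %*% chol2inv(Rh)
  logdet <- 2 * sum(log(diag(Rt))) - 2 * sum(log(diag(Rh)))
  sum(diag(M)) - logdet - m
}

#' Frobenius norm of the difference of two matrices
#'
#' @param K_true,K_hat matrices of equal shape.
#' @return non-negative scalar.
#' @export
frobenius_diff <- function(K_true, K_hat) {
  if (!all(dim(K_hat) == dim(K_true))) stop("shape mismatch")
  sqrt(sum((K_true - K_hat)^2))
}

#' Support-recovery confusion of an estimated precision matrix
#'
#' Classifies each unordered off-diagonal pair as "positive" iff its
#' absolute entry exceeds `tol`, and scores the estimate against the truth:
#' specificity TN/(TN+FP), sensitivity TP/(TP+FN) and Youden's index
#' SPE + SEN - 1.  When a class is empty the corresponding rate is defined
#' as 1.
#'
#' @param K_true,K_hat m x m symmetric matrices.
#' @param tol nonzero threshold; 0 for estimators with exact structural
#'   zeros.
#' @return list with counts `tp`, `tn`, `fp`, `fn` and rates `spe`, `sen`,
#'   `youden`.
#' @export
support_confusion <- function(K_true, K_hat, tol = 0) {
  if (!all(dim(K_hat) == dim(K_true))) stop("shape mismatch")
  stopifnot(tol >= 0)
  up <- upper.tri(K_true)
  truth <- abs(K_true[up]) > tol
  est <- abs(K_hat[up]) > tol
  tp <- sum(est & truth); fn <- sum(!est & truth)
  fp <- sum(est & !truth); tn <- sum(!est & !truth)
  sen <- if (tp + fn > 0L) tp / (tp + fn) else 1
  spe <- if (tn + fp > 0L) tn / (tn + fp) else 1
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       spe = spe, sen = sen, youden = spe + sen - 1)
}

#' Score an estimated network against the truth
#'
#' Convenience wrapper returning Stein loss, Frobenius distance and the
#' support-recovery rates in one list.
#'
#' @inheritParams support_confusion
#' @return list with `stein`, `frob`, `spe`, `sen`, `youden` and the
#'   confusion counts.
#' @export
score_network <- function(K_true, K_hat, tol = 0) {
  sc <- support_confusion(K_true, K_hat, tol)
  c(list(stein = stein_loss(K_true, K_hat),
         frob = frobenius_diff(K_true, K_hat)), sc)
}
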