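#' Multi-class cross-entropy
#'
#' `L = -sum_i y_i log(p_i)` for a one-hot truth vector and a predicted
#' probability vector. Probabilities are clipped at `1e-7` before the
#' logarithm; the prediction must sum to one within `1e-5`.
#'
#' @param y_true one-hot numeric vector of length K.
#' @param y_pred probability vector of length K.
#' @return non-negative scalar loss.
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))   # log(2)
#' @export
cross_entropy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (abs(sum(y_pred) - 1) > 1e-5) {
    stop("y_pred must sum to 1 (got ", sum(y_pred), ")")
  }
  p <- pmin(pmax(y_pred, 1e-7), 1)
  -sum(y_true * log(p))
}

#' Label-smoothing cross-entropy for a binary output
#'
#' The smoothed binary loss
#' `L = -[(1 - eps) * y * log(p) + eps * (1 - y) * log(1 - p)]`:
#' the target-class weight is softened from 1 to `1 - eps` and the
#' off-target term enters with weight `eps`, suppressing overconfident
#' predictions. At `eps = 0` the positive-class term reduces to the binary
#' cross-entropy of the positive class. Note the form is asymmetric: a
#' negative example (`y = 0`) contributes only `eps * log(1 - p)`.
#'
#' @param y true label, 0 or 1 (vectorized).
#' @param p predicted positive-class probability in (0, 1) (vectorized).
#' @param epsilon smoothing factor in `[0, 1)`.
#' @return per-sample loss values.
#' @export
smooth_ce <- function(y, p, epsilon = 0.1) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -((1 - epsilon) * y * log(p) + epsilon * (1 - y) * log(1 - p))
}

#' Regularized label-smoothing loss
#'
#' Adds an L2 penalty on the predicted probability distribution to
#' [smooth_ce()]: `L = smooth_ce + lambda * (p^2 + (1 - p)^2)` per sample
#' (the squared L2 norm of the binary output distribution `(p, 1 - p)`),
#' averaged over the batch. The penalty is minimized at `p = 0.5`, pulling
#' the model away from saturated outputs.
#'
#' @inheritParams smooth_ce
#' @param lambda regularization coefficient, `>= 0`.
#' @param reduce return the batch mean (`TRUE`, default) or per-sample values.
#' @return scalar mean loss (or per-sample vector).
#' @export
reg_smooth_loss <- function(y, p, epsilon = 0.1, lambda = 1e-4,
                            reduce = TRUE) {
  if (lambda < 0) stop("lambda must be non-negative")
  l <- smooth_ce(y, p, epsilon) + lambda * (p^2 + (1 - p)^2)
  if (reduce) mean(l) else l
}

# analytic d(mean loss)/dp for the training loop; p unclipped except in logs
reg_smooth_grad <- function(y, p, epsilon, lambda) {
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  g <- -((1 - epsilon) * y / pc - epsilon * (1 - y) / (1 - pc)) +
    lambda * (4 * pc - 2)
  g / length(y)
}
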