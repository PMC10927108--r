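#' Tracking reconstruction loss (masked-image binary cross-entropy)
#'
#' Binary cross-entropy between the tracking decoder's sigmoid reconstruction
#' and the target image (the input masked with the center-cell segmentation,
#' rescaled to \[0, 1\]). The per-pixel sum is normalised by the number of
#' pixels `W0 * H0` and additionally averaged over channels (the channels are
#' replicas of the grayscale content).
#'
#' @param y target array, values in \[0, 1\] (zero outside the mask).
#' @param y_hat predicted array of identical shape, values in (0, 1).
#' @param eps probabilities are clamped to \[eps, 1 - eps\] before the logs.
#' @return non-negative scalar loss.
#' @export
tracking_loss <- function(y, y_hat, eps = 1e-7) {
  if (!identical(dim(y), dim(y_hat)) || length(y) != length(y_hat)) {
    stop("tracking_loss: shape mismatch between target and prediction")
  }
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Classification loss (one-hot binary cross-entropy)
#'
#' Binary cross-entropy between a one-hot stage target and the per-class
#' sigmoid outputs, averaged over the number of classes. Both the positive
#' (true class) and the negative (other classes) terms contribute.
#'
#' @param y one-hot numeric vector.
#' @param y_hat per-class probabilities in (0, 1), same length.
#' @param eps clamp applied to `y_hat` before the logs.
#' @return non-negative scalar loss.
#' @export
classification_loss <- function(y, y_hat, eps = 1e-7) {
  if (length(y) != length(y_hat)) {
    stop("classification_loss: length mismatch")
  }
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-entropy loss for the frame-independent classifier
#'
#' Only the positive (true class) term of the per-class cross-entropy,
#' normalised by the number of classes: `-(1/N) * sum(y_c * log(y_hat_c))`.
#' The argmax decision rule is unaffected by the `1/N` factor.
#'
#' @inheritParams classification_loss
#' @return non-negative scalar loss.
#' @export
cross_entropy_loss <- function(y, y_hat, eps = 1e-7) {
  if (length(y) != length(y_hat)) {
    stop("cross_entropy_loss: length mismatch")
  }
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -sum(y * log(p)) / length(y)
}

#' Total training loss
#'
#' Weighted sum of the tracking and classification losses,
#' `L_track + lambda_wt * L_cls`. The recurrent models use this combined
#' objective; the frame-independent classifier optimises the classification
#' loss alone.
#'
#' @param l_track tracking loss (scalar, >= 0).
#' @param l_cls classification loss (scalar, >= 0).
#' @param lambda_wt non-negative weighting factor.
#' @return scalar total loss.
#' @export
total_loss <- function(l_track, l_cls, lambda_wt) {
  if (lambda_wt < 0) stop("total_loss: lambda_wt must be non-negative")
  l_track + lambda_wt * l_cls
}
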