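#' Overlap metrics for binary masks
#'
#' `dice(y, t) = 2|Y intersect T| / (|Y| + |T|)` and
#' `iou(y, t) = |Y intersect T| / |Y union T|`, the standard overlap scores
#' between a predicted mask Y and a ground truth T; cardinalities count
#' pixels. For binary masks the two are linked by
#' `dice = 2 * iou / (1 + iou)`.
#'
#' When both masks are empty the metrics are defined as 1.0: a correct
#' "no polyp" prediction on an objectless frame is a perfect prediction,
#' not a failure — the situation the sigmoid-averaged pipeline exists to
#' permit.
#'
#' @param y predicted [binary_mask()].
#' @param t ground-truth [binary_mask()], same shape.
#' @return a scalar in \[0, 1\].
#' @name overlap-metrics
NULL

#' @rdname overlap-metrics
#' @export
dice <- function(y, t) {
  y <- binary_mask(y); t <- binary_mask(t)
  assert_same_shape(y, t, "masks")
  sy <- sum(y); st <- sum(t)
  if (sy + st == 0) return(1.0)
  2 * sum(y * t) / (sy + st)
}

#' @rdname overlap-metrics
#' @export
iou <- function(y, t) {
  y <- binary_mask(y); t <- binary_mask(t)
  assert_same_shape(y, t, "masks")
  inter <- sum(y * t)
  uni <- sum(y) + sum(t) - inter
  if (uni == 0) return(1.0)
  inter / uni
}

#' IoU loss
#'
#' `1 - iou(y, t)`: 0 at a pixel-perfect prediction, 1 for disjoint
#' non-empty masks.
#'
#' @inheritParams dice
#' @return a scalar in \[0, 1\].
#' @export
iou_loss <- function(y, t) {
  1 - iou(y, t)
}

#' Mean of a per-image metric over a test set
#'
#' @param values non-empty numeric vector of per-image metric values.
#' @return their arithmetic mean.
#' @export
dataset_mean <- function(values) {
  if (length(values) == 0L) stopf("cannot average an empty metric list")
  mean(as.numeric(values))
}
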