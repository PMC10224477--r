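#' Head rules: collapse a stack of intermediate masks to one probability mask
#'
#' Segmentation networks with deep supervision emit several pre-sigmoid
#' prediction grids per image (2 for Polyp-PVT-style heads, 4 for
#' HSNet-style). Two rules turn them into a single probability mask:
#'
#' * `aggregate_avg_sigmoid()` — the sigmoid-averaged rule
#'   \deqn{(1/n) \sum_i \sigma(P_i),} which passes each mask through the
#'   logistic function *first* and averages the results. Because each term
#'   is bounded in (0, 1), no single saturated head can pin the output to
#'   an extreme, so the fused mask keeps graded confidence.
#' * `aggregate_sum_sigmoid()` — \eqn{\sigma(\sum_i P_i)}, the conventional
#'   rule. Head logits routinely reach magnitudes of tens to hundreds;
#'   summing them drives the sigmoid even deeper into saturation and the
#'   output becomes almost binary, which makes downstream averaging behave
#'   like voting.
#'
#' The two rules coincide exactly at n = 1.
#'
#' @param stack a [mask_stack()].
#' @return a [prob_mask()] with the stack's shape.
#' @examples
#' st <- mask_stack(list(matrix(2, 1, 1), matrix(4, 1, 1)))
#' aggregate_avg_sigmoid(st)  # (sigmoid(2) + sigmoid(4)) / 2
#' aggregate_sum_sigmoid(st)  # sigmoid(6)
#' @name head-rules
NULL

#' @rdname head-rules
#' @export
aggregate_avg_sigmoid <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  s <- Reduce(`+`, lapply(stack, function(h) sigmoid(unclass(h))))
  prob_mask(s / n_heads(stack))
}

#' @rdname head-rules
#' @export
aggregate_sum_sigmoid <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  prob_mask(sigmoid(Reduce(`+`, lapply(stack, unclass))))
}

#' Min-max normalize a probability mask to span [0, 1]
#'
#' `(mask - min) / (max - min)`. This is the output layer the
#' sigmoid-averaged pipeline removes: it forces the mask to attain both 0
#' and 1 somewhere, i.e. the network "always finds a foreground object" —
#' wrong on frames that contain no polyp. A constant mask (the objectless
#' pathology) therefore raises an error rather than returning an arbitrary
#' grid; surfacing that degenerate case is the point of keeping the
#' operation around as a baseline.
#'
#' @param mask a [prob_mask()].
#' @return a [prob_mask()] whose minimum is exactly 0 and maximum
#'   exactly 1.
#' @export
minmax_normalize <- function(mask) {
  stopifnot(inherits(mask, "prob_mask"))
  r <- range(mask)
  if (r[2] - r[1] <= 0) {
    stopf(paste("min-max normalization is undefined on a constant mask",
                "(objectless frame): max == min == %g"), r[1])
  }
  prob_mask((unclass(mask) - r[1]) / (r[2] - r[1]))
}

#' Fuse member probability masks by (weighted) pixelwise averaging
#'
#' The sum rule is `fuse()` with equal weights; the weighted sum rule uses
#' the supplied weights. Weights are normalized internally, so specs may
#' carry unnormalized integers, and scaling all weights by a positive
#' constant leaves the output unchanged.
#'
#' @param masks non-empty list of [prob_mask()] sharing one shape.
#' @param weights numeric vector, one weight >= 0 per mask, sum > 0.
#'   Default: equal weights (the sum rule).
#' @return the fused [prob_mask()].
#' @examples
#' a <- prob_mask(matrix(0.2, 1, 1)); b <- prob_mask(matrix(0.4, 1, 1))
#' fuse(list(a, b))              # 0.3
#' fuse(list(a, b), c(1, 3))     # 0.35
#' @export
fuse <- function(masks, weights = NULL) {
  if (!is.list(masks) || length(masks) == 0L) {
    stopf("fuse needs a non-empty list of masks")
  }
  masks <- lapply(masks, prob_mask)
  for (m in masks) assert_same_shape(masks[[1]], m, "masks to fuse")
  if (is.null(weights)) weights <- rep(1, length(masks))
  if (length(weights) != length(masks)) {
    stopf("need one weight per mask (%d masks, %d weights)",
          length(masks), length(weights))
  }
  if (any(weights < 0)) stopf("fusion weights must be >= 0")
  if (sum(weights) <= 0) stopf("fusion weights must not all be zero")
  weights <- weights / sum(weights)
  out <- matrix(0, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) out <- out + weights[i] * unclass(masks[[i]])
  # convex combination of [0,1] grids; clamp only guards rounding at 1
  prob_mask(clamp01(out))
}

#' Equal-per-method member weights
#'
#' When an ensemble mixes methods with different member counts (e.g. 8
#' CNN members next to 4 + 4 transformer members), weighting every member
#' equally would let the larger method dominate. This rule gives each
#' *method* the same total weight: a member of method m gets
#' `1 / (M * n_m)` where M is the number of methods and `n_m` the member
#' count of method m. The returned weights sum to 1.
#'
#' @param method_sizes integer vector of members per method, all >= 1.
#' @return numeric vector of per-member weights, concatenated in method
#'   order.
#' @examples
#' equal_method_weights(c(4, 4))     # eight members, 0.125 each
#' equal_method_weights(c(8, 4, 4))  # 1/24 x8, 1/12 x4, 1/12 x4
#' @export
equal_method_weights <- function(method_sizes) {
  if (length(method_sizes) == 0L) stopf("need at least one method")
  method_sizes <- as.integer(method_sizes)
  if (any(method_sizes < 1L)) stopf("every method needs >= 1 member")
  M <- length(method_sizes)
  unlist(lapply(method_sizes, function(nm) rep(1 / (M * nm), nm)))
}

# Resolve the stored stack an ensemble member holds for one image: either
# an in-memory named list under $stacks, or a <image_id>.tif under $path.
member_stack <- function(member, image_id) {
  if (!is.null(member$stacks)) {
    st <- member$stacks[[image_id]]
    if (is.null(st)) stopf("member has no stack for image '%s'", image_id)
    return(if (inherits(st, "mask_stack")) st else mask_stack(st))
  }
  if (!is.null(member$path)) {
    f <- file.path(member$path, paste0(image_id, ".tif"))
    if (!file.exists(f)) {
      f2 <- file.path(member$path, paste0(image_id, ".tiff"))
      if (!file.exists(f2)) stopf("member has no stack file for '%s'", image_id)
      f <- f2
    }
    return(read_logit_stack(f, image_id = image_id))
  }
  stopf("ensemble member carries neither in-memory stacks nor a path")
}

apply_head_rule <- function(stack, head_rule) {
  switch(head_rule,
    avg_sigmoid = aggregate_avg_sigmoid(stack),
    sum_sigmoid = aggregate_sum_sigmoid(stack),
    sum_sigmoid_normalized = minmax_normalize(aggregate_sum_sigmoid(stack)),
    stopf("unknown head rule '%s'", head_rule)
  )
}

#' Run an ensemble on one image
#'
#' Applies the spec's head rule to every member's logit stack for
#' `image_id`, then fuses the per-member probability masks with the spec's
#' weights. With `head_rule = "avg_sigmoid"` this is the proposed
#' smoother-fusion pipeline; with `"sum_sigmoid_normalized"` it reproduces
#' the original-network baseline (sigmoid of summed heads, min-max
#' normalized).
#'
#' @param spec an [ensemble_spec()].
#' @param image_id string key identifying the image in every member's
#'   stack store.
#' @return the fused [prob_mask()].
#' @export
run_ensemble <- function(spec, image_id) {
  stopifnot(inherits(spec, "ensemble_spec"))
  masks <- lapply(spec$members, function(m) {
    apply_head_rule(member_stack(m, image_id), spec$head_rule)
  })
  w <- if (spec$fusion_rule == "weighted_sum") spec$weights else NULL
  fuse(masks, w)
}

#' Threshold a probability mask to a binary mask
#'
#' Pixels strictly greater than `threshold` become 1. The default 0.5 is
#' the sigmoid decision boundary.
#'
#' @param mask a [prob_mask()].
#' @param threshold scalar in (0, 1).
#' @return a [binary_mask()].
#' @export
binarize <- function(mask, threshold = 0.5) {
  stopifnot(inherits(mask, "prob_mask"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stopf("threshold must lie strictly inside (0, 1)")
  }
  binary_mask((unclass(mask) > threshold) * 1)
}
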