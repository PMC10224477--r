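#' Core mask containers
#'
#' The package works with four grid types, all stored as plain numeric
#' matrices indexed \code{[row, col]} (origin top-left, row-major) and tagged
#' with an S3 class so invariants are enforced at construction:
#'
#' * \code{logit_mask} — a pre-sigmoid prediction grid from one supervision
#'   head of a segmentation network (an "intermediate mask"). Values are
#'   unbounded real logits and must be finite.
#' * \code{prob_mask} — a probability grid, every value in \[0, 1\].
#' * \code{binary_mask} — a \{0, 1\} grid (prediction Y or ground truth T).
#' * \code{weight_map} — per-pixel loss weights, all >= 1 under the
#'   boundary-emphasis convention of [weight_map()].
#'
#' Violating inputs raise an error; nothing is silently coerced.
#'
#' @param values numeric matrix (height x width).
#' @param image_id optional string identifying the source image.
#' @return the validated matrix with the corresponding class attached.
#' @name mask-types
NULL

#' @rdname mask-types
#' @export
logit_mask <- function(values, image_id = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(dim(values)) != 2L) {
    stopf("logit_mask values must be a 2-D numeric grid")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stopf("logit_mask must have height >= 1 and width >= 1")
  }
  if (!all(is.finite(values))) {
    stopf("logit_mask values must all be finite")
  }
  structure(values, image_id = image_id, class = c("logit_mask", "matrix"))
}

#' @rdname mask-types
#' @export
prob_mask <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(dim(values)) != 2L) {
    stopf("prob_mask values must be a 2-D numeric grid")
  }
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    stopf("prob_mask values must lie in [0, 1]")
  }
  structure(values, class = c("prob_mask", "matrix"))
}

#' @rdname mask-types
#' @export
binary_mask <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(dim(values)) != 2L) {
    stopf("binary_mask values must be a 2-D numeric grid")
  }
  if (anyNA(values) || !all(values %in% c(0, 1))) {
    stopf("binary_mask values must be 0 or 1")
  }
  structure(values, class = c("binary_mask", "matrix"))
}

#' @rdname mask-types
#' @export
weight_map_values <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(dim(values)) != 2L) {
    stopf("weight_map values must be a 2-D numeric grid")
  }
  if (anyNA(values) || any(values < 1)) {
    stopf("weight map values must all be >= 1")
  }
  structure(values, class = c("weight_map", "matrix"))
}

#' Stack of intermediate masks from one network
#'
#' A \code{mask_stack} holds the ordered pre-sigmoid heads a network emits
#' for one image: 1 for a HarDNet-MSEG-style model, 2 for Polyp-PVT-style,
#' 4 for HSNet-style. All heads must share one shape.
#'
#' @param heads a list of matrices or `logit_mask` objects, or a single
#'   matrix (treated as one head).
#' @param image_id optional string identifying the source image.
#' @return object of class \code{mask_stack}: a list of `logit_mask` heads
#'   with attributes \code{n} (head count) and \code{image_id}.
#' @examples
#' st <- mask_stack(list(matrix(0, 4, 4), matrix(1, 4, 4)))
#' n_heads(st)  # 2
#' @export
mask_stack <- function(heads, image_id = NULL) {
  if (is.matrix(heads)) heads <- list(heads)
  if (!is.list(heads) || length(heads) < 1L) {
    stopf("mask_stack needs at least one head (n >= 1)")
  }
  heads <- lapply(heads, logit_mask)
  shp <- dim(heads[[1]])
  for (h in heads) assert_same_shape(heads[[1]], h, "mask_stack heads")
  structure(heads, n = length(heads), image_id = image_id,
            class = "mask_stack")
}

#' @rdname mask_stack
#' @param x a \code{mask_stack}.
#' @export
n_heads <- function(x) {
  stopifnot(inherits(x, "mask_stack"))
  attr(x, "n")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("mask_stack: %d head(s), %d x %d logits", attr(x, "n"),
              d[1], d[2]))
  id <- attr(x, "image_id")
  if (!is.null(id)) cat(sprintf(" [%s]", id))
  cat("\n")
  rng <- range(unlist(lapply(x, range)))
  cat(sprintf("  logit range: [%.3g, %.3g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Training-run provenance for an ensemble member
#'
#' Describes how a member network was produced: topology family, optimizer,
#' augmentation strategy (DA1 = 3 geometric transforms, DA2 = 13 transforms),
#' learning-rate schedule ("a" = constant 1e-4; "b" = 5e-5 decaying to 5e-6
#' after 30 epochs) and whether the sigmoid-averaged head rule (SM) was used.
#' Configs are provenance metadata only — no training happens in this package.
#'
#' @param family one of "hardnet_mseg", "polyp_pvt", "hsnet",
#'   "deeplabv3plus", "synthetic".
#' @param optimizer one of "SGD", "Adam", "AdamW".
#' @param da "DA1" or "DA2".
#' @param lr_schedule "a" or "b".
#' @param smoothing logical; TRUE for the sigmoid-averaged head rule.
#' @param epochs,batch_size integers recorded for provenance.
#' @return object of class \code{member_config}.
#' @export
member_config <- function(family = "synthetic",
                          optimizer = c("AdamW", "Adam", "SGD"),
                          da = c("DA1", "DA2"),
                          lr_schedule = c("a", "b"),
                          smoothing = TRUE,
                          epochs = 100L,
                          batch_size = 8L) {
  families <- c("hardnet_mseg", "polyp_pvt", "hsnet", "deeplabv3plus",
                "synthetic")
  if (!family %in% families) {
    stopf("unknown family '%s' (expected one of: %s)", family,
          paste(families, collapse = ", "))
  }
  optimizer <- match.arg(optimizer)
  da <- match.arg(da)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(is.logical(smoothing), length(smoothing) == 1L)
  structure(
    list(family = family, optimizer = optimizer, da = da,
         lr_schedule = lr_schedule, smoothing = smoothing,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size)),
    class = "member_config"
  )
}

#' @export
print.member_config <- function(x, ...) {
  cat(sprintf("member_config: %s / %s / %s / LR %s / SM %s\n",
              x$family, x$optimizer, x$da, x$lr_schedule,
              if (x$smoothing) "yes" else "no"))
  invisible(x)
}

#' Assemble an ensemble specification
#'
#' An \code{ensemble_spec} names the members of an ensemble, how each
#' member's intermediate masks collapse to one probability mask (the head
#' rule) and how the member masks fuse (sum or weighted sum). Member
#' weights are normalized to sum to 1; missing weights default to 1 before
#' normalization, so the plain sum rule is the default.
#'
#' @param members list; each element a list with at least one of
#'   \code{stacks} (named list of [mask_stack()] keyed by image id) or
#'   \code{path} (directory of per-image logit TIFFs), plus optional
#'   \code{config} ([member_config()]) and \code{weight} (>= 0).
#' @param fusion_rule "sum" or "weighted_sum".
#' @param head_rule "avg_sigmoid" (the sigmoid-averaged rule),
#'   "sum_sigmoid", or "sum_sigmoid_normalized" (sigmoid of the summed heads
#'   followed by min-max normalization — the original-network baseline).
#' @return object of class \code{ensemble_spec} with normalized
#'   \code{weights}.
#' @seealso [load_ensemble_spec()] to read one from YAML, [run_ensemble()].
#' @export
ensemble_spec <- function(members,
                          fusion_rule = c("sum", "weighted_sum"),
                          head_rule = c("avg_sigmoid", "sum_sigmoid",
                                        "sum_sigmoid_normalized")) {
  fusion_rule <- match.arg(fusion_rule)
  head_rule <- match.arg(head_rule)
  if (!is.list(members) || length(members) < 1L) {
    stopf("ensemble_spec needs a non-empty member list")
  }
  w <- vapply(members, function(m) {
    if (is.null(m$weight)) 1.0 else as.numeric(m$weight)
  }, numeric(1))
  if (any(w < 0)) stopf("member weights must be >= 0")
  if (sum(w) <= 0) stopf("member weights must not all be zero")
  structure(
    list(members = members, weights = w / sum(w),
         fusion_rule = fusion_rule, head_rule = head_rule),
    class = "ensemble_spec"
  )
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("ensemble_spec: %d member(s), fusion '%s', head rule '%s'\n",
              length(x$members), x$fusion_rule, x$head_rule))
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}
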