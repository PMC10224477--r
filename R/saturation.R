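#' Non-saturation rate of fused masks
#'
#' A fused pixel is *saturated* when its value is within 0.001 of 0 or 1 —
#' equivalently when the driving logit has magnitude >= 6.9, since
#' sigmoid(6.9) rounds to 0.999. Saturated pixels carry almost no graded
#' confidence into an ensemble, which is why the conventional
#' sum-then-sigmoid head turns averaging into voting.
#'
#' For `rule = "sum"` a pixel is non-saturated when `|sum_i P_i| <
#' threshold`. For `rule = "avg"` the averaged mask has no single
#' pre-sigmoid logit, so saturation is assessed in the probability domain:
#' a pixel is non-saturated when its averaged probability lies strictly
#' inside `(sigmoid(-threshold), sigmoid(threshold))`. The two definitions
#' coincide at n = 1. Rates are pooled over all pixels of all images (one
#' rate per model over the whole set, not a per-image average).
#'
#' @param stacks non-empty list of [mask_stack()] (one per image).
#' @param rule "avg" or "sum".
#' @param threshold saturation threshold in logit units; default 6.9.
#' @return the fraction of non-saturated pixels, in \[0, 1\].
#' @export
nonsaturation_rate <- function(stacks, rule = c("avg", "sum"),
                               threshold = 6.9) {
  rule <- match.arg(rule)
  if (!is.list(stacks) || length(stacks) == 0L) {
    stopf("need at least one stack")
  }
  stacks <- lapply(stacks, function(s) {
    if (inherits(s, "mask_stack")) s else mask_stack(s)
  })
  ok <- 0; total <- 0
  lo <- sigmoid(-threshold); hi <- sigmoid(threshold)
  for (s in stacks) {
    if (rule == "sum") {
      z <- Reduce(`+`, lapply(s, unclass))
      ok <- ok + sum(abs(z) < threshold)
    } else {
      p <- unclass(aggregate_avg_sigmoid(s))
      ok <- ok + sum(p > lo & p < hi)
    }
    total <- total + length(s[[1]])
  }
  ok / total
}

#' Per-head logit statistics and saturation rates over an image set
#'
#' For each head position i, computes over the image set:
#' * `avg_min` / `avg_max` — the mean over images of that head's per-image
#'   minimum / maximum logit;
#' * `max_min` — the maximum over images of the per-image minima;
#' * `min_max` — the minimum over images of the per-image maxima;
#'
#' plus the pooled non-saturation rates under both fusion rules
#' ([nonsaturation_rate()]). `min_max` far above the threshold means every
#' image contains strongly saturated foreground pixels in that head.
#'
#' @param stacks non-empty list of [mask_stack()] sharing one head count.
#' @param threshold saturation threshold in logit units; default 6.9.
#' @return object of class `saturation_report`: a list with `per_head`
#'   (data frame with columns head, min_max, avg_max, avg_min, max_min),
#'   `sat_avg_rate`, `sat_sum_rate`, `threshold`, `n_images`.
#' @export
saturation_report <- function(stacks, threshold = 6.9) {
  if (!is.list(stacks) || length(stacks) == 0L) {
    stopf("need at least one stack")
  }
  stacks <- lapply(stacks, function(s) {
    if (inherits(s, "mask_stack")) s else mask_stack(s)
  })
  n <- n_heads(stacks[[1]])
  for (s in stacks) {
    if (n_heads(s) != n) {
      stopf("all stacks must share one head count (got %d and %d)",
            n, n_heads(s))
    }
  }
  per_image_min <- sapply(stacks, function(s) vapply(s, min, numeric(1)))
  per_image_max <- sapply(stacks, function(s) vapply(s, max, numeric(1)))
  # sapply gives n_heads x n_images (or a vector when n = 1)
  per_image_min <- matrix(per_image_min, nrow = n)
  per_image_max <- matrix(per_image_max, nrow = n)
  per_head <- data.frame(
    head = seq_len(n),
    min_max = apply(per_image_max, 1, min),
    avg_max = apply(per_image_max, 1, mean),
    avg_min = apply(per_image_min, 1, mean),
    max_min = apply(per_image_min, 1, max)
  )
  structure(
    list(per_head = per_head,
         sat_avg_rate = nonsaturation_rate(stacks, "avg", threshold),
         sat_sum_rate = nonsaturation_rate(stacks, "sum", threshold),
         threshold = threshold,
         n_images = length(stacks)),
    class = "saturation_report"
  )
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf(
    "saturation_report: %d image(s), %d head(s), threshold %.2f logits\n",
    x$n_images, nrow(x$per_head), x$threshold))
  ph <- x$per_head
  ph[-1] <- lapply(ph[-1], function(v) signif(v, 4))
  print(ph, row.names = FALSE)
  cat(sprintf("non-saturated pixels: avg rule %.2f%%, sum rule %.2f%%\n",
              100 * x$sat_avg_rate, 100 * x$sat_sum_rate))
  invisible(x)
}

#' @export
as.data.frame.saturation_report <- function(x, ...) {
  out <- x$per_head
  out$sat_avg_rate <- x$sat_avg_rate
  out$sat_sum_rate <- x$sat_sum_rate
  out
}
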