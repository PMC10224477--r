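# Inference-resolution protocol and dataset evaluation. Networks consume
# 352 x 352 inputs; predicted masks are scaled back to each ground
# truth's native size before scoring, so the metrics are computed at the
# dataset's original resolution.

INFERENCE_SIZE <- 352L

#' Resize an image to the 352 x 352 inference resolution
#'
#' Bilinear resize of an RGB array or grayscale matrix to exactly
#' 352 x 352.
#'
#' @param image matrix (height x width) or array (height x width x
#'   channels), values in \[0, 1\].
#' @return the resized image with the same number of channels.
#' @export
resize_for_inference <- function(image) {
  if (length(image) == 0L || is.null(dim(image))) {
    stopf("cannot resize an empty image")
  }
  out <- EBImage::resize(as_eb(image), w = INFERENCE_SIZE,
                         h = INFERENCE_SIZE, filter = "bilinear")
  from_eb(out)
}

#' Scale a probability mask back to its original size
#'
#' Bilinear resize to `original_size`, then clipped to \[0, 1\] (bilinear
#' interpolation of values already in \[0, 1\] can only leave the range
#' through floating-point rounding).
#'
#' @param mask a [prob_mask()].
#' @param original_size integer vector `c(height, width)`, both >= 1.
#' @return a [prob_mask()] of size `original_size`.
#' @export
restore_mask <- function(mask, original_size) {
  mask <- prob_mask(mask)
  original_size <- as.integer(original_size)
  if (length(original_size) != 2L || any(original_size < 1L)) {
    stopf("original_size must be c(height, width), both >= 1")
  }
  if (identical(dim(mask)[1:2], original_size)) {
    return(mask)
  }
  out <- EBImage::resize(as_eb(unclass(mask)), w = original_size[2],
                         h = original_size[1], filter = "bilinear")
  prob_mask(clamp01(from_eb(out)))
}

#' Evaluate predicted masks against ground truths
#'
#' Pairs prediction and ground-truth PNGs by base name; each prediction
#' (an 8-bit probability mask) is restored to its ground truth's native
#' size if needed, binarized at `threshold`, and scored with [dice()] and
#' [iou()]. Dataset means are the arithmetic means over images.
#'
#' @param pred_dir directory of prediction PNGs (grayscale, probabilities
#'   quantized to 8 bits).
#' @param gt_dir directory of ground-truth PNGs (nominally \{0, 255\}).
#' @param threshold binarization threshold in (0, 1).
#' @param dataset_name label carried into the result.
#' @return object of class `eval_result`: list with `per_image` (data
#'   frame: image_id, dice, iou, sorted by image_id), `mean_dice`,
#'   `mean_iou`, `dataset_name`.
#' @export
evaluate <- function(pred_dir, gt_dir, threshold = 0.5,
                     dataset_name = basename(gt_dir)) {
  preds <- sort(list.files(pred_dir, pattern = "\\.png$"))
  gts <- sort(list.files(gt_dir, pattern = "\\.png$"))
  if (length(preds) == 0L || length(gts) == 0L) {
    stopf("no PNG files to evaluate in '%s' / '%s'", pred_dir, gt_dir)
  }
  if (!setequal(preds, gts)) {
    orphans <- c(setdiff(preds, gts), setdiff(gts, preds))
    stopf("unpaired files: %s", paste(orphans, collapse = ", "))
  }
  rows <- lapply(preds, function(f) {
    gt <- read_binary_mask(file.path(gt_dir, f))
    p <- png::readPNG(file.path(pred_dir, f))
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p <- prob_mask(p)
    if (!identical(dim(p)[1:2], dim(gt)[1:2])) {
      p <- restore_mask(p, dim(gt)[1:2])
    }
    y <- binarize(p, threshold)
    data.frame(image_id = tools::file_path_sans_ext(f),
               dice = dice(y, gt), iou = iou(y, gt),
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  per_image <- per_image[order(per_image$image_id), , drop = FALSE]
  rownames(per_image) <- NULL
  structure(
    list(per_image = per_image,
         mean_dice = dataset_mean(per_image$dice),
         mean_iou = dataset_mean(per_image$iou),
         dataset_name = dataset_name),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result '%s': %d image(s)\n", x$dataset_name,
              nrow(x$per_image)))
  cat(sprintf("  mean Dice %.4f, mean IoU %.4f\n", x$mean_dice, x$mean_iou))
  invisible(x)
}

#' @export
as.data.frame.eval_result <- function(x, ...) x$per_image
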