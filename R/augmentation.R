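# Mask-preserving data augmentation.
#
# Two strategies: DA1 (3 deterministic geometric transforms) and DA2 (13
# transforms including motion blur and shadow overlays, seeded). Geometric
# transforms are applied identically to image and mask (nearest-neighbor
# for the mask so it stays binary, zero/background fill); photometric
# transforms touch the image only.

aug_pair <- function(image, mask, transform_id) {
  structure(list(image = image, mask = binary_mask(mask),
                 transform_id = transform_id),
            class = "augmented_pair")
}

#' @export
print.augmented_pair <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("augmented_pair '%s': %d x %d, %s image\n", x$transform_id,
              d[1], d[2],
              if (length(dim(x$image)) == 3L) "RGB" else "grayscale"))
  invisible(x)
}

# ---- exact index-mapping transforms ----------------------------------

flip_ud_grid <- function(m) {
  if (length(dim(m)) == 3L) m[rev(seq_len(nrow(m))), , , drop = FALSE]
  else m[rev(seq_len(nrow(m))), , drop = FALSE]
}

flip_lr_grid <- function(m) {
  if (length(dim(m)) == 3L) m[, rev(seq_len(ncol(m))), , drop = FALSE]
  else m[, rev(seq_len(ncol(m))), drop = FALSE]
}

# counterclockwise quarter turn: out[i, j] = in[j, W + 1 - i], out is W x H
rot90_ccw_grid <- function(m) {
  if (length(dim(m)) == 3L) {
    out <- array(0, c(ncol(m), nrow(m), dim(m)[3]))
    for (ch in seq_len(dim(m)[3])) out[, , ch] <- rot90_ccw_grid(m[, , ch])
    return(out)
  }
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

rot90_cw_grid <- function(m) {
  if (length(dim(m)) == 3L) {
    out <- array(0, c(ncol(m), nrow(m), dim(m)[3]))
    for (ch in seq_len(dim(m)[3])) out[, , ch] <- rot90_cw_grid(m[, , ch])
    return(out)
  }
  t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
}

# ---- resampling transforms -------------------------------------------

# Sample `m` at real-valued source coordinates (sr, sc), 1-based; points
# outside the grid take `fill`.
sample_grid <- function(m, sr, sc, interp = c("bilinear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  if (length(dim(m)) == 3L) {
    out <- array(0, c(dim(sr), dim(m)[3]))
    for (ch in seq_len(dim(m)[3])) {
      out[, , ch] <- sample_grid(m[, , ch], sr, sc, interp, fill)
    }
    return(out)
  }
  H <- nrow(m); W <- ncol(m)
  outside <- sr < 1 | sr > H | sc < 1 | sc > W
  if (interp == "nearest") {
    ri <- pmin(pmax(round(sr), 1), H)
    ci <- pmin(pmax(round(sc), 1), W)
    out <- m[cbind(as.vector(ri), as.vector(ci))]
  } else {
    r0 <- pmin(pmax(floor(sr), 1), H); r1 <- pmin(r0 + 1, H)
    c0 <- pmin(pmax(floor(sc), 1), W); c1 <- pmin(c0 + 1, W)
    fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
    idx <- function(r, c) m[cbind(as.vector(r), as.vector(c))]
    out <- (1 - fr) * (1 - fc) * idx(r0, c0) +
      (1 - fr) * fc * idx(r0, c1) +
      fr * (1 - fc) * idx(r1, c0) +
      fr * fc * idx(r1, c1)
  }
  out[as.vector(outside)] <- fill
  matrix(out, nrow(sr), ncol(sr))
}

# Apply an inverse-mapped warp given source-coordinate fields; image
# bilinear, mask nearest, both filled with background.
warp_pair <- function(image, mask, sr, sc) {
  list(image = sample_grid(image, sr, sc, "bilinear", fill = 0),
       mask = sample_grid(unclass(mask), sr, sc, "nearest", fill = 0))
}

# Source-coordinate fields for an affine map: for each output pixel,
# src = A %*% (out - center) + center (A is the inverse transform).
affine_fields <- function(H, W, A) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  list(sr = A[1, 1] * r + A[1, 2] * c + cy,
       sc = A[2, 1] * r + A[2, 2] * c + cx)
}

rotate_pair <- function(image, mask, angle_deg) {
  th <- angle_deg * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f <- affine_fields(nrow(mask), ncol(mask), A)
  warp_pair(image, mask, f$sr, f$sc)
}

shear_pair <- function(image, mask, k) {
  A <- matrix(c(1, 0, k, 1), 2, 2)  # rows shifted proportionally to column
  f <- affine_fields(nrow(mask), ncol(mask), A)
  warp_pair(image, mask, f$sr, f$sc)
}

scale_pair <- function(image, mask, s) {
  A <- diag(2) / s  # s > 1 zooms in (crop), s < 1 zooms out (pad)
  f <- affine_fields(nrow(mask), ncol(mask), A)
  warp_pair(image, mask, f$sr, f$sc)
}

elastic_pair <- function(image, mask, alpha = 8, sigma = 6) {
  H <- nrow(mask); W <- ncol(mask)
  smooth_field <- function() {
    f <- from_eb(EBImage::gblur(as_eb(matrix(stats::rnorm(H * W), H, W)),
                                sigma = sigma))
    f / max(abs(f), 1e-12) * alpha
  }
  dr <- smooth_field(); dc <- smooth_field()
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  warp_pair(image, mask, r + dr, c + dc)
}

# ---- photometric transforms (mask untouched) -------------------------

conv_image <- function(image, k) {
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3])) {
      out[, , ch] <- conv_image(image[, , ch], k)
    }
    return(out)
  }
  clamp01(from_eb(EBImage::filter2(as_eb(image), k, boundary = "replicate")))
}

motion_blur_image <- function(image, length_px = 9, angle_deg = 0) {
  half <- (length_px - 1) / 2
  th <- angle_deg * pi / 180
  ts <- seq(-half, half, by = 0.5)
  rr <- round(ts * sin(th)) + half + 1
  cc <- round(ts * cos(th)) + half + 1
  k <- matrix(0, length_px, length_px)
  k[cbind(pmin(pmax(rr, 1), length_px), pmin(pmax(cc, 1), length_px))] <- 1
  conv_image(image, k / sum(k))
}

gaussian_blur_image <- function(image, sigma = 1.5) {
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3])) {
      out[, , ch] <- gaussian_blur_image(image[, , ch], sigma)
    }
    return(out)
  }
  clamp01(from_eb(EBImage::gblur(as_eb(image), sigma = sigma)))
}

# Darken the interior of a random convex polygon; soft edge from a small
# Gaussian blur of the polygon's indicator.
shadow_image <- function(image, n_vertices = 5, strength = 0.5) {
  H <- if (length(dim(image)) == 3L) dim(image)[1] else nrow(image)
  W <- if (length(dim(image)) == 3L) dim(image)[2] else ncol(image)
  cy <- stats::runif(1, 0.25 * H, 0.75 * H)
  cx <- stats::runif(1, 0.25 * W, 0.75 * W)
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.15, 0.45) * min(H, W)
  vy <- cy + rad * sin(ang); vx <- cx + rad * cos(ang)
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- matrix(TRUE, H, W)
  for (i in seq_len(n_vertices)) {
    j <- if (i == n_vertices) 1L else i + 1L
    # vertices are angle-sorted (counterclockwise), so the interior is on
    # one consistent side of every edge
    cross <- (vx[j] - vx[i]) * (r - vy[i]) - (vy[j] - vy[i]) * (c - vx[i])
    inside <- inside & (cross >= 0)
  }
  soft <- from_eb(EBImage::gblur(as_eb(inside * 1), sigma = 2))
  shade <- 1 - strength * clamp01(soft)
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- image[, , ch] * shade
    clamp01(out)
  } else {
    clamp01(image * shade)
  }
}

brightness_contrast_image <- function(image, gain = 1.2, bias = 0.05) {
  clamp01(gain * (image - 0.5) + 0.5 + bias)
}

gaussian_noise_image <- function(image, sd = 0.03) {
  clamp01(image + array(stats::rnorm(length(image), sd = sd), dim(image)))
}

# ---- strategies -------------------------------------------------------

#' DA1: basic geometric augmentation
#'
#' Produces exactly three synthetic image/mask pairs per input: an
#' up/down flip, a left/right flip, and a 90-degree counterclockwise
#' rotation (which swaps height and width). All three are applied
#' identically to image and mask; masks stay binary.
#'
#' @param image RGB array (height x width x 3) or grayscale matrix with
#'   values in \[0, 1\].
#' @param mask [binary_mask()] with the image's height and width.
#' @return list of 3 `augmented_pair` objects with transform ids
#'   `flip_ud`, `flip_lr`, `rot90_ccw`.
#' @export
da1 <- function(image, mask) {
  mask <- binary_mask(mask)
  assert_same_shape(image, mask, "image and mask")
  list(
    aug_pair(flip_ud_grid(image), flip_ud_grid(unclass(mask)), "flip_ud"),
    aug_pair(flip_lr_grid(image), flip_lr_grid(unclass(mask)), "flip_lr"),
    aug_pair(rot90_ccw_grid(image), rot90_ccw_grid(unclass(mask)),
             "rot90_ccw")
  )
}

#' DA2: sophisticated 13-way augmentation
#'
#' Produces exactly 13 synthetic pairs per input: the DA1 flips and
#' quarter turns in both directions, a random rotation (within +/- 35
#' degrees), a shear, a scale (0.8-1.2 with crop/pad), an elastic warp,
#' and five photometric transforms — motion blur, Gaussian blur, a shadow
#' polygon overlay, brightness/contrast jitter, and Gaussian noise.
#' Geometric members transform the mask identically (nearest-neighbor, so
#' it stays binary); photometric members leave the mask untouched. All
#' stochastic parameters are drawn from a private stream, so the output is
#' a pure function of (image, mask, seed).
#'
#' @inheritParams da1
#' @param seed integer controlling every stochastic parameter.
#' @return list of 13 `augmented_pair` objects.
#' @export
da2 <- function(image, mask, seed = 0L) {
  mask <- binary_mask(mask)
  assert_same_shape(image, mask, "image and mask")
  mm <- unclass(mask)
  with_seed(seed, {
    angle <- stats::runif(1, -35, 35)
    shear_k <- stats::runif(1, -0.2, 0.2)
    scale_s <- stats::runif(1, 0.8, 1.2)
    blur_angle <- stats::runif(1, 0, 180)
    out <- list(
      aug_pair(flip_ud_grid(image), flip_ud_grid(mm), "flip_ud"),
      aug_pair(flip_lr_grid(image), flip_lr_grid(mm), "flip_lr"),
      aug_pair(rot90_ccw_grid(image), rot90_ccw_grid(mm), "rot90_ccw"),
      aug_pair(rot90_cw_grid(image), rot90_cw_grid(mm), "rot90_cw")
    )
    p <- rotate_pair(image, mask, angle)
    out[[5]] <- aug_pair(p$image, p$mask, "random_rotation")
    p <- shear_pair(image, mask, shear_k)
    out[[6]] <- aug_pair(p$image, p$mask, "shear")
    p <- scale_pair(image, mask, scale_s)
    out[[7]] <- aug_pair(p$image, p$mask, "scale")
    p <- elastic_pair(image, mask)
    out[[8]] <- aug_pair(p$image, p$mask, "elastic_warp")
    out[[9]] <- aug_pair(motion_blur_image(image, 9, blur_angle), mm,
                         "motion_blur")
    out[[10]] <- aug_pair(gaussian_blur_image(image), mm, "gaussian_blur")
    out[[11]] <- aug_pair(shadow_image(image), mm, "shadow_polygon_overlay")
    out[[12]] <- aug_pair(
      brightness_contrast_image(image, gain = stats::runif(1, 0.8, 1.3),
                                bias = stats::runif(1, -0.08, 0.08)),
      mm, "brightness_contrast_jitter")
    out[[13]] <- aug_pair(gaussian_noise_image(image), mm, "gaussian_noise")
    out
  })
}

#' Augment a directory of paired images and masks
#'
#' Pairs image and mask PNGs by base name, writes the originals plus the
#' DA1 (3) or DA2 (13) synthetics per pair under `out_dir/images` and
#' `out_dir/masks` (synthetics suffixed `__<transform_id>`), and records
#' provenance in `out_dir/manifest.csv`.
#'
#' @param image_dir,mask_dir directories of PNGs paired by base name.
#' @param strategy "DA1" or "DA2".
#' @param out_dir output directory (created if missing).
#' @param seed integer; DA2 draws per-image seeds from it.
#' @return the manifest data frame (columns image, mask, source_id,
#'   transform_id), invisibly.
#' @export
augment_dataset <- function(image_dir, mask_dir,
                            strategy = c("DA1", "DA2"),
                            out_dir, seed = 0L) {
  strategy <- match.arg(strategy)
  imgs <- sort(list.files(image_dir, pattern = "\\.png$"))
  msks <- sort(list.files(mask_dir, pattern = "\\.png$"))
  if (!setequal(imgs, msks)) {
    orphans <- c(setdiff(imgs, msks), setdiff(msks, imgs))
    stopf("unpaired files: %s", paste(orphans, collapse = ", "))
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  emit <- function(img, msk, name, source_id, tid) {
    ip <- file.path(out_dir, "images", paste0(name, ".png"))
    mp <- file.path(out_dir, "masks", paste0(name, ".png"))
    png::writePNG(img, ip)
    write_mask_png(binary_mask(msk), mp)
    data.frame(image = ip, mask = mp, source_id = source_id,
               transform_id = tid, stringsAsFactors = FALSE)
  }
  for (i in seq_along(imgs)) {
    base <- tools::file_path_sans_ext(imgs[i])
    img <- png::readPNG(file.path(image_dir, imgs[i]))
    if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
    msk <- read_binary_mask(file.path(mask_dir, msks[i]))
    rows[[length(rows) + 1L]] <-
      emit(img, msk, base, base, "original")
    pairs <- if (strategy == "DA1") {
      da1(img, msk)
    } else {
      da2(img, msk, seed = seed + i)
    }
    for (p in pairs) {
      rows[[length(rows) + 1L]] <-
        emit(p$image, p$mask, paste0(base, "__", p$transform_id), base,
             p$transform_id)
    }
  }
  manifest <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(image = character(), mask = character(),
               source_id = character(), transform_id = character(),
               stringsAsFactors = FALSE)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
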