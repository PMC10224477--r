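# Seeded generators of polyp-like scenes, multi-head logit stacks and
# degraded member predictions. These emulate the *statistical* structure
# the fusion machinery cares about — logit magnitudes, boundary softness,
# member diversity — not photorealistic endoscopy.

#' Scene generator configuration
#'
#' @param height,width frame size in pixels.
#' @param n_objects number of elliptical blobs; 0 gives an objectless
#'   frame (the case min-max normalization mishandles).
#' @param object_scale nominal blob diameter as a fraction of the frame's
#'   shorter side.
#' @param texture_noise_sd intensity SD of the background texture.
#' @param seed integer seed; generators are pure functions of it.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height = 128L, width = 128L, n_objects = 1L,
                         object_scale = 0.2, texture_noise_sd = 0.05,
                         seed = 1L) {
  if (n_objects < 0L) stopf("n_objects must be >= 0")
  if (object_scale <= 0 || object_scale >= 1) {
    stopf("object_scale must lie in (0, 1)")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_objects = as.integer(n_objects),
                 object_scale = object_scale,
                 texture_noise_sd = texture_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Head-model configuration
#'
#' Parameterizes how a network head converts a ground truth into
#' pre-sigmoid logits: `head_i = gain_i * tanh(d / softness_i) + bias +
#' noise`, with d the signed distance (pixels) to the mask boundary
#' (positive inside). Gains set the logit magnitude scale — real
#' supervision heads reach per-image extremes anywhere from about 2.5 up
#' to about 160 logits — and softness sets how blurred the head's edges
#' are; deeper heads of real networks are visibly softer.
#'
#' @param n_heads number of intermediate masks (1 emulates a
#'   HarDNet-MSEG-style output, 2 Polyp-PVT-style, 4 HSNet-style).
#' @param logit_gain positive gain per head (recycled to `n_heads`).
#' @param boundary_softness softness in pixels per head (recycled).
#' @param noise_sd logit-scale Gaussian noise SD.
#' @param head_bias additive logit bias.
#' @param seed integer seed.
#' @return object of class `head_model_config`.
#' @export
head_model_config <- function(n_heads = 2L, logit_gain = 40,
                              boundary_softness = 3, noise_sd = 0,
                              head_bias = 0, seed = 1L) {
  n_heads <- as.integer(n_heads)
  if (n_heads < 1L) stopf("n_heads must be >= 1")
  logit_gain <- rep_len(as.numeric(logit_gain), n_heads)
  boundary_softness <- rep_len(as.numeric(boundary_softness), n_heads)
  if (any(logit_gain <= 0)) stopf("logit gains must be positive")
  if (any(boundary_softness <= 0)) stopf("boundary softness must be positive")
  structure(list(n_heads = n_heads, logit_gain = logit_gain,
                 boundary_softness = boundary_softness,
                 noise_sd = noise_sd, head_bias = head_bias,
                 seed = as.integer(seed)),
            class = "head_model_config")
}

# union of `n` random ellipses that fit fully inside the frame; returns
# the binary support. Axis jitter is +/- 20% so blob area stays within
# (0.64x, 1.44x) of the nominal ellipse area.
random_ellipse_mask <- function(H, W, n, scale) {
  truth <- matrix(0, H, W)
  if (n == 0L) return(truth)
  r_nom <- scale * min(H, W) / 2
  if (2 * 1.2 * r_nom >= min(H, W)) {
    stopf("objects of scale %.2f do not fit in a %dx%d frame", scale, H, W)
  }
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n)) {
    a <- r_nom * stats::runif(1, 0.8, 1.2)
    b <- r_nom * stats::runif(1, 0.8, 1.2)
    th <- stats::runif(1, 0, pi)
    margin <- max(a, b) + 1
    cy <- stats::runif(1, margin, H - margin)
    cx <- stats::runif(1, margin, W - margin)
    dy <- rows - cy; dx <- cols - cx
    u <- dy * cos(th) + dx * sin(th)
    v <- -dy * sin(th) + dx * cos(th)
    truth[(u / a)^2 + (v / b)^2 <= 1] <- 1
  }
  truth
}

#' Generate a polyp-like synthetic scene
#'
#' Renders smooth elliptical blobs with a radial intensity gradient on a
#' textured, reddish background; the ground truth is the union of blob
#' supports. Deterministic for a given config (seed included).
#'
#' @param cfg a [scene_config()].
#' @return list with `image` (height x width x 3 RGB array in \[0, 1\])
#'   and `truth` (a [binary_mask()]).
#' @export
gen_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  H <- cfg$height; W <- cfg$width
  with_seed(cfg$seed, {
    truth <- random_ellipse_mask(H, W, cfg$n_objects, cfg$object_scale)
    texture <- from_eb(EBImage::gblur(
      as_eb(matrix(stats::rnorm(H * W, sd = 1), H, W)), sigma = 2))
    texture <- texture / max(abs(texture), 1e-12) * cfg$texture_noise_sd
    # interior intensity bump, brighter toward the blob center
    d_in <- from_eb(EBImage::distmap(as_eb(truth)))
    bump <- if (max(d_in) > 0) 0.25 * sqrt(d_in / max(d_in)) else d_in
    base <- c(0.55, 0.32, 0.27)  # mucosa-like tint
    obj <- c(0.30, 0.12, 0.10)   # blobs darker and redder
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      img[, , ch] <- clamp01(base[ch] + texture + truth * (obj[ch] -
        base[ch]) + bump * (ch == 1))
    }
    list(image = img, truth = binary_mask(truth))
  })
}

# signed distance to the mask boundary in pixels: positive inside the
# mask, negative outside. EBImage::distmap treats out-of-frame pixels as
# background, which also covers the all-foreground / all-background cases.
signed_distance <- function(truth) {
  tm <- unclass(truth)
  d_in <- from_eb(EBImage::distmap(as_eb(tm)))
  d_out <- from_eb(EBImage::distmap(as_eb(1 - tm)))
  d_in - d_out
}

#' Generate a multi-head logit stack for a ground truth
#'
#' Each head is `gain_i * tanh(d / softness_i) + bias + noise` with d the
#' signed boundary distance, so logits are positive inside the truth and
#' negative outside (before noise and bias), saturate toward +/- gain away
#' from the boundary, and soften with `boundary_softness` — a smooth
#' stand-in for real supervision heads, whose deeper masks have visibly
#' more blurred edges than the fused output.
#'
#' @param truth a [binary_mask()].
#' @param cfg a [head_model_config()].
#' @return a [mask_stack()] with `cfg$n_heads` heads.
#' @export
gen_head_stack <- function(truth, cfg) {
  truth <- binary_mask(truth)
  stopifnot(inherits(cfg, "head_model_config"))
  d <- signed_distance(truth)
  with_seed(cfg$seed, {
    heads <- lapply(seq_len(cfg$n_heads), function(i) {
      h <- cfg$logit_gain[i] * tanh(d / cfg$boundary_softness[i]) +
        cfg$head_bias
      if (cfg$noise_sd > 0) {
        h <- h + matrix(stats::rnorm(length(d), sd = cfg$noise_sd),
                        nrow(d), ncol(d))
      }
      h
    })
    mask_stack(heads)
  })
}

#' Generate degraded member predictions for ensemble experiments
#'
#' Produces `k` independent imperfect probability masks for one ground
#' truth, each degraded by (i) a random translation of the truth
#' (boundary jitter), (ii) random false-positive / false-negative
#' elliptical blobs, and (iii) smooth confidence noise. With all error
#' parameters zero every member equals the truth exactly. Members are
#' independent given the seed, so averaging them dilutes the blob errors
#' below the decision threshold — the mechanism by which sum-rule fusion
#' beats its average member.
#'
#' @param truth a [binary_mask()].
#' @param k number of members, >= 1.
#' @param error_cfg list with `jitter_px` (max |translation| per axis,
#'   pixels), `blob_rate` (probability of each of a false-positive and a
#'   false-negative blob), `blob_scale` (blob diameter as a fraction of
#'   the short side), `noise_sd` (confidence noise amplitude).
#' @param seed integer seed.
#' @return list of `k` [prob_mask()] objects.
#' @export
gen_member_predictions <- function(truth, k,
                                   error_cfg = list(jitter_px = 2,
                                                    blob_rate = 0.3,
                                                    blob_scale = 0.12,
                                                    noise_sd = 0.15),
                                   seed = 1L) {
  truth <- binary_mask(truth)
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  defaults <- list(jitter_px = 0, blob_rate = 0, blob_scale = 0.1,
                   noise_sd = 0)
  ec <- utils::modifyList(defaults, error_cfg)
  H <- nrow(truth); W <- ncol(truth)
  tm <- unclass(truth)
  shift_mask <- function(m, dy, dx) {
    out <- matrix(0, H, W)
    src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
    ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      m <- tm
      if (ec$jitter_px > 0) {
        m <- shift_mask(m, sample(-ec$jitter_px:ec$jitter_px, 1),
                        sample(-ec$jitter_px:ec$jitter_px, 1))
      }
      if (ec$blob_rate > 0) {
        if (stats::runif(1) < ec$blob_rate) {          # false positive
          m <- pmax(m, random_ellipse_mask(H, W, 1L, ec$blob_scale))
        }
        if (stats::runif(1) < ec$blob_rate) {          # false negative
          m <- pmin(m, 1 - random_ellipse_mask(H, W, 1L, ec$blob_scale))
        }
      }
      if (ec$noise_sd > 0) {
        nf <- from_eb(EBImage::gblur(
          as_eb(matrix(stats::rnorm(H * W), H, W)), sigma = 3))
        nf <- nf / stats::sd(nf) * ec$noise_sd
        m <- clamp01(m + nf)
      }
      prob_mask(m)
    })
  })
}
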