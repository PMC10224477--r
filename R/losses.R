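# same-size k x k average pooling with replicated edges, via a summed-area
# table; exact for binary inputs and valid for kernels larger than the grid
box_mean <- function(m, k) {
  if (k == 1L) return(m)
  H <- nrow(m); W <- ncol(m)
  pad <- (k - 1L) %/% 2L
  P <- m[c(rep(1L, pad), seq_len(H), rep(H, pad)),
         c(rep(1L, pad), seq_len(W), rep(W, pad)), drop = FALSE]
  S <- rbind(0, apply(P, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  i <- seq_len(H); j <- seq_len(W)
  (S[i + k, j + k, drop = FALSE] - S[i, j + k, drop = FALSE] -
     S[i + k, j, drop = FALSE] + S[i, j, drop = FALSE]) / k^2
}

#' Boundary-emphasizing pixel weights from average pooling
#'
#' `w = 1 + lam * |avgpool(t) - t|`, where the average pooling uses a
#' `kernel x kernel` window, stride 1, same-size output and replicated
#' edges. The pooled mask equals the mask away from the boundary, so
#' `w = 1` there; wherever the window straddles the mask boundary the
#' pooled value departs from the mask and the weight rises, up to
#' `1 + lam * (1 - 1/kernel^2)`. Training losses weighted this way
#' concentrate on object boundaries, where segmentation errors live.
#'
#' @param t ground-truth [binary_mask()].
#' @param kernel odd window size in pixels; 31 is the convention for
#'   352 x 352 training crops.
#' @param stride only 1 is supported (same-size pooling).
#' @param lam boundary emphasis factor; default 5.
#' @return a weight map (matrix >= 1 everywhere, class `weight_map`).
#' @export
weight_map <- function(t, kernel = 31L, stride = 1L, lam = 5) {
  t <- binary_mask(t)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) {
    stopf("pooling kernel must be odd and >= 1 (got %d)", kernel)
  }
  if (stride != 1L) stopf("only stride 1 average pooling is supported")
  tm <- unclass(t)
  pooled <- box_mean(tm, kernel)
  w <- 1 + lam * abs(pooled - tm)
  # guard the floating-point dust from the summed-area table
  weight_map_values(pmax(w, 1))
}

#' Weighted binary cross-entropy
#'
#' Two-class weighted cross-entropy
#' \deqn{-\sum_i \sum_k w_{ik} T_{ik} \log P_{ik}}
#' with the background class taken as the complement
#' (`P_bg = 1 - P_fg`, `T_bg = 1 - T_fg`) and both classes sharing the
#' pixel weight, which makes the single-sum form equal the full weighted
#' BCE. Reported as the mean over pixels so values are
#' resolution-independent. Predictions are clipped to
#' `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param p predicted [prob_mask()].
#' @param t ground-truth [binary_mask()], same shape.
#' @param w weight map from [weight_map()] (or any matrix >= 1); default
#'   all ones.
#' @return a non-negative scalar.
#' @export
wbce_loss <- function(p, t, w = NULL) {
  p <- prob_mask(p); t <- binary_mask(t)
  assert_same_shape(p, t, "prediction and truth")
  if (is.null(w)) w <- matrix(1, nrow(t), ncol(t))
  assert_same_shape(t, w, "mask and weight map")
  eps <- 1e-7
  pc <- pmin(pmax(unclass(p), eps), 1 - eps)
  tm <- unclass(t); wm <- unclass(w)
  mean(-wm * (tm * log(pc) + (1 - tm) * log(1 - pc)))
}

#' Weighted IoU loss with +1 smoothing
#'
#' \deqn{1 - \frac{1 + \sum_i \sum_k w_{ik} T_{ik} Y_{ik}}
#'              {1 + \sum_i \sum_k w_{ik} (T_{ik} + Y_{ik} - T_{ik} Y_{ik})}}
#' summed over pixels and both classes (foreground and its complement).
#' The +1 in numerator and denominator prevents 0/0 on a correctly
#' predicted empty mask, so an objectless frame predicted empty scores a
#' loss of exactly 0.
#'
#' @param y predicted [prob_mask()] (soft intersection/union).
#' @inheritParams wbce_loss
#' @return a scalar in \[0, 1).
#' @export
wiou_loss <- function(y, t, w = NULL) {
  y <- prob_mask(y); t <- binary_mask(t)
  assert_same_shape(y, t, "prediction and truth")
  if (is.null(w)) w <- matrix(1, nrow(t), ncol(t))
  assert_same_shape(t, w, "mask and weight map")
  ym <- unclass(y); tm <- unclass(t); wm <- unclass(w)
  inter <- sum(wm * tm * ym) + sum(wm * (1 - tm) * (1 - ym))
  union <- sum(wm * (tm + ym - tm * ym)) +
    sum(wm * ((1 - tm) + (1 - ym) - (1 - tm) * (1 - ym)))
  1 - (1 + inter) / (1 + union)
}

#' Structure loss: weighted IoU + weighted BCE
#'
#' The training loss of the HarDNet-MSEG lineage:
#' `structure_loss = wiou_loss + wbce_loss`, both terms sharing one
#' boundary weight map computed from the ground truth. Takes raw logits;
#' the sigmoid is applied internally.
#'
#' @param p_logits a [logit_mask()] (or plain matrix) of pre-sigmoid
#'   predictions.
#' @param t ground-truth [binary_mask()], same shape.
#' @param kernel,lam passed to [weight_map()].
#' @return a non-negative scalar; near 0 for a confident, pixel-perfect
#'   prediction.
#' @export
structure_loss <- function(p_logits, t, kernel = 31L, lam = 5) {
  p_logits <- logit_mask(p_logits)
  t <- binary_mask(t)
  assert_same_shape(p_logits, t, "logits and truth")
  w <- weight_map(t, kernel = kernel, lam = lam)
  p <- prob_mask(sigmoid(unclass(p_logits)))
  wiou_loss(p, t, w) + wbce_loss(p, t, w)
}
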