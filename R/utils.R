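#' Logistic (sigmoid) function
#'
#' \code{sigmoid(x) = 1 / (1 + exp(-x))}, applied elementwise. This is the
#' activation every head rule and saturation diagnostic in the package is
#' expressed in; the saturation threshold convention is that
#' \code{sigmoid(6.9)} rounds to 0.999, so a logit of magnitude 6.9 or more
#' leaves less than 0.001 of graded confidence.
#'
#' @param x numeric vector, matrix or array of logits.
#' @return object of the same shape with values in (0, 1).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(6.9)    # ~0.999
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generators in the package use
# this so they are pure functions of (config, seed) with no global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# ---- bridge between the package's (row, col) = (y from top, x) matrices and
# EBImage's (x, y) Image layout. All EBImage calls go through these two
# helpers so the coordinate convention lives in exactly one place.

as_eb <- function(m) {
  if (length(dim(m)) == 3L) {
    EBImage::Image(aperm(m, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    EBImage::Image(t(m))
  }
}

from_eb <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) aperm(d, c(2L, 1L, 3L)) else t(d)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a)[1:2]
  db <- dim(b)[1:2]
  if (!identical(as.integer(da), as.integer(db))) {
    stopf("%s must share one shape: got %dx%d and %dx%d",
          what, da[1], da[2], db[1], db[2])
  }
  invisible(TRUE)
}
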