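# Shared fixture builders. Everything is generated in code; no binary
# fixtures live on disk.

# deterministic RGB test image with distinguishable entries
make_rgb <- function(h, w) {
  array(seq_len(h * w * 3) / (h * w * 3), c(h, w, 3))
}

# random binary mask of given shape under the current RNG
random_mask <- function(h, w, p = 0.5) {
  binary_mask(matrix(stats::rbinom(h * w, 1, p), h, w))
}

# a small blob-in-the-middle ground truth
blob_mask <- function(h = 32, w = 32, r = 8) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  binary_mask(((rows - h / 2)^2 + (cols - w / 2)^2 <= r^2) * 1)
}

# write a matrix as an 8-bit grayscale PNG, returning the path
write_gray_png <- function(m, path = tempfile(fileext = ".png")) {
  png::writePNG(m, path)
  path
}
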