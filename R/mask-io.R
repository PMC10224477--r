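#' Read a binary ground-truth or prediction mask from PNG
#'
#' Reads an 8-bit grayscale PNG and binarizes it at the midpoint of the
#' 8-bit range: pixel values strictly greater than 127 map to 1, the rest
#' to 0. Ground-truth polyp masks are nominally \{0, 255\}, so the midpoint
#' threshold is insensitive to small encoding artifacts.
#'
#' @param path path to an 8-bit grayscale PNG file.
#' @return a [binary_mask()] with the image's shape preserved.
#' @export
read_binary_mask <- function(path) {
  if (!file.exists(path)) stopf("cannot read mask: no such file '%s'", path)
  v <- tryCatch(png::readPNG(path), error = function(e) {
    stopf("cannot decode PNG '%s': %s", path, conditionMessage(e))
  })
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] %in% c(2L, 4L)) v <- v[, , -dim(v)[3], drop = FALSE]
    if (dim(v)[3] == 1L) {
      v <- v[, , 1L]
    } else {
      stopf("'%s' is not a grayscale image (found %d channels)",
            path, dim(v)[3])
    }
  }
  if (length(dim(v)) != 2L) stopf("'%s' is not a 2-D image", path)
  # readPNG scales 8-bit values k to k/255; k > 127 <=> k/255 > 127/255
  binary_mask((v > 127 / 255) * 1)
}

#' Write a binary or probability mask to 8-bit grayscale PNG
#'
#' Probabilities are quantized to 8 bits on export only; all internal
#' arithmetic stays in double precision.
#'
#' @param mask a [binary_mask()] or [prob_mask()] (any matrix in \[0, 1\]).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- unclass(mask)
  attr(m, "image_id") <- NULL
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stopf("mask values must lie in [0, 1] for PNG export")
  }
  png::writePNG(m, target = path)
  invisible(path)
}

# ---- multi-page float32 TIFF codec for logit stacks -------------------
#
# Logit grids are unbounded reals (deep-head extremes reach the
# hundreds), so they are stored as uncompressed IEEE float32 TIFF, one page
# per head. Reading goes through libtiff (tiff::readTIFF), which returns
# float samples losslessly; writing emits the minimal little-endian layout
# (10 baseline tags + SampleFormat=IEEEFP, single strip per page) because
# tiff::writeTIFF has no float sample-format path.

#' Read a logit stack from a multi-page float TIFF
#'
#' @param path path to a multi-page float32 TIFF, one page per head.
#' @param image_id optional id stored on the stack; defaults to the file's
#'   base name.
#' @return a [mask_stack()] with one head per page.
#' @export
read_logit_stack <- function(path, image_id = NULL) {
  if (!file.exists(path)) stopf("cannot read stack: no such file '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE), error = function(e) {
    stopf("cannot decode TIFF '%s': %s", path, conditionMessage(e))
  })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stopf("'%s' contains no pages", path)
  for (p in pages) {
    if (length(dim(p)) != 2L) stopf("'%s' has a non-2-D page", path)
  }
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  mask_stack(pages, image_id = image_id)
}

#' Write a logit stack to a multi-page float32 TIFF
#'
#' @param stack a [mask_stack()] (or list of matrices / single matrix).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_logit_stack <- function(stack, path) {
  if (!inherits(stack, "mask_stack")) stack <- mask_stack(stack)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) {
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  tag <- function(code, type, count, value) {
    wb(code, 2); wb(type, 2); wb(count, 4)
    if (type == 3L) {           # SHORT, padded to the 4-byte value field
      wb(value, 2); wb(0L, 2)
    } else {                    # LONG
      wb(value, 4)
    }
  }
  n <- length(stack)
  h <- vapply(stack, nrow, integer(1))
  w <- vapply(stack, ncol, integer(1))
  nbytes <- h * w * 4L
  ifd_size <- 2L + 10L * 12L + 4L
  data_off <- integer(n)
  ifd_off <- integer(n)
  pos <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- pos; pos <- pos + nbytes[i]
    ifd_off[i] <- pos;  pos <- pos + ifd_size
  }
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2)
  wb(ifd_off[1], 4)
  for (i in seq_len(n)) {
    # pixel data, row-major as TIFF requires (R matrices are column-major)
    writeBin(as.numeric(t(unclass(stack[[i]]))), con, size = 4,
             endian = "little")
    wb(10L, 2)
    tag(256L, 4L, 1L, w[i])          # ImageWidth
    tag(257L, 4L, 1L, h[i])          # ImageLength
    tag(258L, 3L, 1L, 32L)           # BitsPerSample
    tag(259L, 3L, 1L, 1L)            # Compression: none
    tag(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off[i])   # StripOffsets
    tag(277L, 3L, 1L, 1L)            # SamplesPerPixel
    tag(278L, 4L, 1L, h[i])          # RowsPerStrip
    tag(279L, 4L, 1L, nbytes[i])     # StripByteCounts
    tag(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    wb(if (i < n) ifd_off[i + 1] else 0L, 4)
  }
  invisible(path)
}

#' Load an ensemble specification from YAML
#'
#' The schema mirrors [ensemble_spec()]: a `members` sequence whose entries
#' carry `family`, `optimizer`, `da`, `lr_schedule`, `smoothing`, `path`
#' and `weight` keys (all but `path` optional; missing weights default to
#' 1.0 before normalization), plus top-level `fusion_rule` and `head_rule`.
#'
#' @param path path to a YAML file.
#' @return a validated [ensemble_spec()] with weights normalized to sum
#'   to 1.
#' @export
load_ensemble_spec <- function(path) {
  if (!file.exists(path)) stopf("no such spec file '%s'", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$members) || length(doc$members) == 0L) {
    stopf("ensemble spec '%s' has an empty member list", path)
  }
  members <- lapply(doc$members, function(m) {
    cfg <- member_config(
      family = if (is.null(m$family)) "synthetic" else m$family,
      optimizer = if (is.null(m$optimizer)) "AdamW" else m$optimizer,
      da = if (is.null(m$da)) "DA1" else m$da,
      lr_schedule = if (is.null(m$lr_schedule)) "a" else m$lr_schedule,
      smoothing = if (is.null(m$smoothing)) TRUE else isTRUE(m$smoothing)
    )
    list(config = cfg, path = m$path,
         weight = if (is.null(m$weight)) 1.0 else as.numeric(m$weight))
  })
  ensemble_spec(
    members,
    fusion_rule = if (is.null(doc$fusion_rule)) "sum" else doc$fusion_rule,
    head_rule = if (is.null(doc$head_rule)) "avg_sigmoid" else doc$head_rule
  )
}
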