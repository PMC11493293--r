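# Shared low-level helpers: image plumbing, seed derivation, validation.

#' Convert an image to grayscale
#'
#' Uses the Rec. 601 luma combination `0.299 R + 0.587 G + 0.114 B` for
#' 3-channel input; grayscale matrices pass through unchanged.
#'
#' @param img An `H x W` matrix or `H x W x 3` array with values in
#'   `[0, 255]`.
#' @return An `H x W` numeric matrix in `[0, 255]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) {
    return(img)
  }
  if (is.array(img) && length(dim(img)) == 3L) {
    d <- dim(img)
    if (d[3] == 1L) {
      return(img[, , 1L])
    }
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  abort("`img` must be an H x W matrix or an H x W x 3 array.",
        class = "feedstream_bad_image")
}

# Replicate a grayscale matrix into an H x W x 3 array.
gray_to_rgb <- function(m) {
  array(rep(m, 3L), dim = c(dim(m), 3L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-item seed derivation from a master seed; stays within
# 32-bit signed range, exact in double precision.
derive_seed <- function(master, index, salt = 0) {
  ((master %% 1e6) * 2654435 + salt * 97003 + index * 7919) %% 2147483647 + 1
}

stopifnot_label <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% feeding_classes)) {
    abort(
      paste0("`label` must be one of ", paste(feeding_classes, collapse = ", "), "."),
      class = "feedstream_bad_label"
    )
  }
  label
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(paste0(what, " contains non-finite values."),
          class = "feedstream_nonfinite")
  }
  invisible(x)
}

# Conv/pool output extent under floor arithmetic.
conv_out_len <- function(n, k, stride, pad) {
  floor((n + 2 * pad - k) / stride) + 1
}

#' Read a PNG frame as an 8-bit RGB array
#'
#' @param path Path to a PNG file.
#' @return `H x W x 3` numeric array with values in `[0, 255]`.
#' @keywords internal
read_frame_png <- function(path) {
  px <- png::readPNG(path)
  if (is.matrix(px)) px <- gray_to_rgb(px * 255) else {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE] * 255
    else px <- gray_to_rgb(px[, , 1L] * 255)
  }
  px
}

write_frame_png <- function(img, path) {
  if (is.matrix(img)) img <- gray_to_rgb(img)
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
}
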