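# Spatial stream: binarize frames so bright splash/reflection regions become
# foreground. Two modes are provided because the source method is described
# both as a dual saturation/value threshold rule and as mean-gray
# thresholding; the dual rule is the default.

#' Binarization configuration
#'
#' @param mode `"dual_threshold"` (default): a pixel is foreground when its
#'   saturation is strictly below `t_s` and its value strictly above `t_v`
#'   (both on the 0-255 scale of the hue-saturation-value representation) --
#'   this isolates bright, unsaturated specular splash regions.
#'   `"mean_gray"`: a pixel is foreground when its gray level is `>=` the
#'   image mean (ties map to foreground).
#' @param t_s Saturation threshold, 0-255 (dual mode only).
#' @param t_v Value threshold, 0-255 (dual mode only).
#' @return A `binarization_config` object.
#' @export
binarize_config <- function(mode = c("dual_threshold", "mean_gray"),
                            t_s = 60, t_v = 200) {
  mode <- match.arg(mode)
  if (t_s < 0 || t_s > 255 || t_v < 0 || t_v > 255) {
    abort("Thresholds must lie in [0, 255].", class = "feedstream_bad_config")
  }
  structure(list(mode = mode, t_s = t_s, t_v = t_v),
            class = "binarization_config")
}

#' Binarize an image
#'
#' Output pixels are exactly 0 (background) or 255 (foreground); the 0/255
#' alphabet (rather than 0/1) keeps binary frames round-trippable through
#' image files.
#'
#' @param image `H x W x 3` RGB array or grayscale matrix, 8-bit scale.
#' @param config A [binarize_config()].
#' @return `H x W` numeric matrix with values in `{0, 255}`.
#' @export
binarize <- function(image, config = binarize_config()) {
  if (is.null(image) || length(image) == 0L) {
    abort("Empty image.", class = "feedstream_bad_image")
  }
  if (config$mode == "mean_gray") {
    g <- as_gray(image)
    out <- matrix(0, nrow(g), ncol(g))
    out[g >= mean(g)] <- 255
    return(out)
  }
  img <- if (is.matrix(image)) gray_to_rgb(image) else image
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1L]), g = as.vector(img[, , 2L]),
    b = as.vector(img[, , 3L]), maxColorValue = 255
  )
  s255 <- hsv["s", ] * 255
  v255 <- hsv["v", ] * 255
  fg <- (s255 < config$t_s) & (v255 > config$t_v)
  matrix(ifelse(fg, 255, 0), d[1], d[2])
}

#' Foreground fraction of a binary image
#'
#' Diagnostic for the extent of the reflective splash area.
#'
#' @param binary `H x W` matrix with values in `{0, 255}`.
#' @return Proportion of foreground (255) pixels, in `[0, 1]`.
#' @export
foreground_fraction <- function(binary) {
  if (!all(binary %in% c(0, 255))) {
    abort("Input is not a 0/255 binary image.", class = "feedstream_bad_image")
  }
  mean(binary == 255)
}
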