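# Class activation maps (classic formulation): the classifier-weighted sum of
# the final convolutional feature maps of a network with a global-average-
# pooling head, upsampled to the input size. Applicable to both 2D streams.

#' Class activation map for an image
#'
#' Runs the model in inference mode, takes the feature maps entering the
#' global average pool, weights each channel by the classifier weight of
#' `target_class`, keeps the positive part, bilinearly upsamples to the input
#' size and min-max normalizes to `[0, 1]` (a constant map normalizes to all
#' zeros). The overlay blends a blue-to-red colormap of the heatmap onto the
#' input -- deeper red marks regions the classifier weighs more for that
#' class.
#'
#' @param model A `stream_model` of kind `"residual"` (the architecture whose
#'   global-average-pooling head the classic formulation requires).
#' @param image Input image (`H x W x 3` array, `[0, 255]`).
#' @param target_class Class to explain (`none`/`weak`/`strong`).
#' @param keep_raw Keep the pre-normalization weighted map (for diagnostics).
#' @return An `activation_map`: list with `heatmap` (`H x W`, in `[0, 1]`),
#'   `target_class`, `overlay` (`H x W x 3`, `[0, 255]`) and optionally `raw`.
#' @export
class_activation_map <- function(model, image, target_class,
                                 keep_raw = FALSE) {
  if (!inherits(model, "stream_model") || model$kind != "residual") {
    abort("CAM requires a residual model with a global-average-pooling head.",
          class = "feedstream_bad_model")
  }
  stopifnot_label(target_class)
  xb <- scale_input(as_input_batch(image, model$kind), model$kind)
  check_input_shape(model, xb)
  gap_i <- which(vapply(model$layers, function(l) l$type == "gap", logical(1)))
  dense_i <- which(vapply(model$layers, function(l) l$type == "dense", logical(1)))
  if (!length(gap_i) || !length(dense_i)) {
    abort("Model lacks a global-pooling classifier head.",
          class = "feedstream_bad_model")
  }
  # feature maps entering the pool: re-run the prefix up to the gap layer
  h <- xb
  for (i in seq_len(gap_i - 1L)) {
    h <- layer_fw(model$layers[[i]], h, training = FALSE)$y
  }
  fmap <- h[, , , 1]                       # Hf x Wf x C
  wfc <- model$layers[[dense_i[length(dense_i)]]]$w
  cls <- match(target_class, model$classes)
  weights <- wfc[cls, ]
  raw <- apply(sweep(fmap, 3, weights, `*`), c(1, 2), sum)
  raw_pos <- pmax(raw, 0)
  d <- dim(image)[1:2]
  up <- EBImage::resize(raw_pos, w = d[1], h = d[2])
  rng <- range(up)
  heatmap <- if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    matrix(0, d[1], d[2])
  } else {
    (up - rng[1]) / diff(rng)
  }
  img <- if (is.matrix(image)) gray_to_rgb(image) else image
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(heatmap))
  heat_rgb <- array(c(matrix(cols[, 1], d[1], d[2]),
                      matrix(cols[, 2], d[1], d[2]),
                      matrix(cols[, 3], d[1], d[2])), dim = c(d, 3L))
  overlay <- clamp(0.5 * img + 0.5 * heat_rgb, 0, 255)
  out <- list(heatmap = heatmap, target_class = target_class,
              overlay = overlay)
  if (keep_raw) out$raw <- raw
  structure(out, class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> class %s, %dx%d, mass %.3f\n",
              x$target_class, nrow(x$heatmap), ncol(x$heatmap),
              mean(x$heatmap)))
  invisible(x)
}

#' Plot an activation map overlay
#'
#' @param object An `activation_map`.
#' @param ... Unused.
#' @return A ggplot raster of the overlay.
#' @export
autoplot.activation_map <- function(object, ...) {
  d <- dim(object$heatmap)
  df <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$value <- as.vector(object$heatmap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(colours = c("blue", "cyan", "yellow", "red"),
                                  limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = paste0("CAM: ", object$target_class))
}
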