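# Temporal stream: dense optical flow from the brightness-constancy
# constraint Ix*u + Iy*v + It = 0, solved with a global smoothness penalty
# (Horn-Schunck-type energy), and HSV color-wheel rendering of flow fields.

#' Spatiotemporal intensity gradients of a frame pair
#'
#' Partial derivatives of gray-level intensity along X (columns), Y (rows) and
#' T. `Ix` and `Iy` are central differences (replicated edges) averaged over
#' the two frames; `It` is the per-pixel difference `frame_b - frame_a`.
#'
#' @param frame_a,frame_b Same-shape grayscale matrices (or RGB arrays,
#'   converted via [as_gray()]), consecutive in time.
#' @return A `gradient_triple`: list with `H x W` matrices `Ix`, `Iy`, `It`.
#' @export
spatiotemporal_gradients <- function(frame_a, frame_b) {
  a <- as_gray(frame_a); b <- as_gray(frame_b)
  if (!identical(dim(a), dim(b))) {
    abort("Frames must have the same shape.", class = "feedstream_shape_mismatch")
  }
  m <- (a + b) / 2
  h <- nrow(m); w <- ncol(m)
  # central differences with replicated borders
  left <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  down <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  structure(list(Ix = (right - left) / 2, Iy = (down - up) / 2, It = b - a),
            class = "gradient_triple")
}

#' Estimate dense optical flow between two frames
#'
#' Minimizes the global energy combining the brightness-constancy data term
#' `(Ix u + Iy v + It)^2` with a quadratic smoothness penalty on the flow
#' field, weighted by `smoothness_weight^2`, using Gauss-Seidel sweeps that
#' solve each pixel's 2x2 system exactly. The objective is therefore
#' non-increasing over iterations (exposed as `attr(flow, "energy")`).
#'
#' Uniform brightness changes between frames violate the constancy
#' assumption; no robustness to them is claimed.
#'
#' @param frame_a,frame_b Same-shape grayscale/RGB frames.
#' @param smoothness_weight Positive smoothness weight (default 15).
#' @param n_iterations Number of Gauss-Seidel sweeps (default 100).
#' @return A `flow_field`: list with matrices `u` (px/frame along X, i.e.
#'   columns) and `v` (px/frame along Y, i.e. rows), with the per-sweep
#'   energy trace as attribute `energy`.
#' @export
estimate_flow <- function(frame_a, frame_b, smoothness_weight = 15,
                          n_iterations = 100L) {
  if (smoothness_weight <= 0 || n_iterations < 1) {
    abort("`smoothness_weight` must be > 0 and `n_iterations` >= 1.",
          class = "feedstream_bad_config")
  }
  g <- spatiotemporal_gradients(frame_a, frame_b)
  assert_finite(c(g$Ix, g$Iy, g$It), "Input frames")
  sol <- hs_flow(g$Ix, g$Iy, g$It, smoothness_weight, as.integer(n_iterations))
  structure(list(u = sol$u, v = sol$v),
            class = "flow_field", energy = sol$energy, gradients = g)
}

#' Flow-field energy under the global-smoothness objective
#'
#' @param flow A `flow_field` (or list with `u`, `v`).
#' @param gradients A `gradient_triple` from [spatiotemporal_gradients()].
#' @param smoothness_weight The smoothness weight used.
#' @return The scalar energy value.
#' @export
flow_energy <- function(flow, gradients, smoothness_weight) {
  u <- flow$u; v <- flow$v
  r <- gradients$Ix * u + gradients$Iy * v + gradients$It
  h <- nrow(u); w <- ncol(u)
  dvert <- sum((u[-1, ] - u[-h, ])^2) + sum((v[-1, ] - v[-h, ])^2)
  dhorz <- sum((u[, -1] - u[, -w])^2) + sum((v[, -1] - v[, -w])^2)
  sum(r^2) + smoothness_weight^2 * (dvert + dhorz)
}

#' Render a flow field as an RGB image
#'
#' Standard HSV color-wheel convention: hue encodes the flow angle
#' `atan2(v, u)` over the full wheel, saturation encodes magnitude relative to
#' `max_magnitude` (value channel stays at 1), so zero flow renders as the
#' constant reference color white and opposite directions are 180 degrees
#' apart on the wheel. Hue is invariant to joint scaling of `(u, v)`;
#' saturation is monotone in magnitude.
#'
#' @param flow A `flow_field`.
#' @param max_magnitude Magnitude mapped to full saturation (px/frame), or
#'   `NULL` for the per-image maximum (guarded against zero).
#' @return `H x W x 3` numeric array in `[0, 255]`.
#' @export
flow_to_image <- function(flow, max_magnitude = NULL) {
  u <- flow$u; v <- flow$v
  assert_finite(c(u, v), "Flow field")
  mag <- sqrt(u^2 + v^2)
  m <- max_magnitude %||% max(mag)
  if (m <= 0) m <- 1
  hue <- (atan2(v, u) / (2 * pi)) %% 1
  sat <- clamp(mag / m, 0, 1)
  cols <- grDevices::hsv(h = hue, s = sat, v = 1)
  rgb <- grDevices::col2rgb(cols)
  d <- dim(u)
  array(c(matrix(rgb[1, ], d[1], d[2]),
          matrix(rgb[2, ], d[1], d[2]),
          matrix(rgb[3, ], d[1], d[2])), dim = c(d, 3L))
}

#' Flow images for a whole sequence
#'
#' Renders one flow image per consecutive frame pair.
#'
#' @param seq A [frame_sequence()].
#' @inheritParams estimate_flow
#' @inheritParams flow_to_image
#' @return List of `length(seq) - 1` RGB arrays.
#' @export
sequence_flow_images <- function(seq, smoothness_weight = 15,
                                 n_iterations = 100L, max_magnitude = NULL) {
  g <- lapply(seq$frames, as_gray)
  lapply(seq_len(length(g) - 1L), function(i) {
    fl <- estimate_flow(g[[i]], g[[i + 1L]],
                        smoothness_weight = smoothness_weight,
                        n_iterations = n_iterations)
    flow_to_image(fl, max_magnitude = max_magnitude)
  })
}
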