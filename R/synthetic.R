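# Synthetic feeding-scene generator.
#
# Emulates the three feeding-intensity classes as seen by an overhead camera:
# fish are dark ellipses advected by a seeded random walk, feed-induced
# splashes are bright near-saturated disks with Poisson arrivals and short
# lifetimes, and the water surface carries i.i.d. Gaussian shimmer. Brightness
# encodes splash (not fish) because the spatial stream keys on bright
# reflective regions.

#' Scene configuration for the synthetic generator
#'
#' @param frame_size Integer vector `(height, width)` in pixels, both >= 32.
#' @param n_frames Number of frames to render (>= 2).
#' @param fps Nominal frame rate, frames/second (metadata only).
#' @param n_fish Number of moving fish particles.
#' @param motion_scale Mean fish step length, px/frame. 0 freezes the school.
#' @param splash_rate Expected number of new splash disks per frame
#'   (Poisson arrivals).
#' @param splash_radius Nominal splash disk radius, px.
#' @param surface_noise_sigma Standard deviation of per-pixel Gaussian
#'   surface shimmer, gray levels.
#' @param background_level Water background gray level, 0-255.
#' @param seed Integer seed; identical configurations (including seed)
#'   render bit-identical frame stacks.
#' @return A `scene_config` object (a validated list).
#' @seealso [class_preset()], [generate_sequence()]
#' @export
scene_config <- function(frame_size = c(270L, 480L), n_frames = 48L, fps = 24,
                         n_fish = 8L, motion_scale = 0, splash_rate = 0,
                         splash_radius = 0, surface_noise_sigma = 1,
                         background_level = 120, seed = 1L) {
  cfg <- list(
    frame_size = as.integer(frame_size), n_frames = as.integer(n_frames),
    fps = fps, n_fish = as.integer(n_fish), motion_scale = motion_scale,
    splash_rate = splash_rate, splash_radius = splash_radius,
    surface_noise_sigma = surface_noise_sigma,
    background_level = background_level, seed = as.integer(seed)
  )
  if (length(cfg$frame_size) != 2L || any(cfg$frame_size < 32L)) {
    abort("`frame_size` must be two integers, each >= 32.",
          class = "feedstream_bad_config")
  }
  if (cfg$n_frames < 2L) {
    abort("`n_frames` must be >= 2.", class = "feedstream_bad_config")
  }
  rates <- c(cfg$motion_scale, cfg$splash_rate, cfg$splash_radius,
             cfg$surface_noise_sigma, cfg$fps)
  if (any(rates < 0) || cfg$n_fish < 0L) {
    abort("All rates and scales must be >= 0.", class = "feedstream_bad_config")
  }
  structure(cfg, class = "scene_config")
}

# Per-class generator presets. Magnitudes are free parameters chosen once to
# realize the class semantics (calm / localized ripples / large fast splashes)
# with a strict none < weak < strong ordering of motion, splash rate, splash
# size and surface shimmer.
.class_presets <- list(
  none   = list(motion_scale = 0,   splash_rate = 0,   splash_radius = 0,
                surface_noise_sigma = 1),
  weak   = list(motion_scale = 1.5, splash_rate = 0.8, splash_radius = 3,
                surface_noise_sigma = 2.5),
  strong = list(motion_scale = 4,   splash_rate = 4,   splash_radius = 6,
                surface_noise_sigma = 5)
)

#' Scene preset for a feeding-intensity class
#'
#' Returns a [scene_config()] realizing one of the three class definitions:
#' `none` (no response, calm water: zero motion, zero splash), `weak`
#' (localized feeding, visible surface fluctuation) or `strong` (free movement
#' between food, fierce swimming stirring the water). Motion scale, splash
#' rate and splash radius are strictly ordered none < weak < strong.
#'
#' @param label One of `"none"`, `"weak"`, `"strong"`.
#' @param ... Overrides passed to [scene_config()] (e.g. `frame_size`,
#'   `n_frames`, `seed`).
#' @return A `scene_config`.
#' @export
class_preset <- function(label, ...) {
  stopifnot_label(label)
  preset <- .class_presets[[label]]
  dots <- list(...)
  args <- utils::modifyList(preset, dots)
  do.call(scene_config, args)
}

# Rasterize an axis-aligned filled ellipse onto `canvas` (in place value set).
draw_ellipse <- function(canvas, cy, cx, ry, rx, angle, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- max(ry, rx)
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(canvas)
  dy <- ys - cy
  dx <- xs - cx
  ca <- cos(angle); sa <- sin(angle)
  # rotate offsets into the ellipse frame
  yy <- outer(dy, dx, function(a, b) a * ca + b * sa)
  xx <- outer(dy, dx, function(a, b) -a * sa + b * ca)
  mask <- (yy / ry)^2 + (xx / rx)^2 <= 1
  sub <- canvas[ys, xs, drop = FALSE]
  sub[mask] <- value
  canvas[ys, xs] <- sub
  canvas
}

draw_disk <- function(canvas, cy, cx, r, value) {
  draw_ellipse(canvas, cy, cx, r, r, 0, value)
}

#' Render a labeled synthetic feeding scene
#'
#' Renders `config$n_frames` grayscale frames (replicated to 3 channels) of a
#' simulated water surface: dark fish ellipses advected by a seeded,
#' heading-persistent random walk with mean step `motion_scale`; bright
#' (>= 250 gray) splash disks arriving as a Poisson process with rate
#' `splash_rate`/frame and lifetimes of 2-4 frames; i.i.d. Gaussian pixel
#' noise of sd `surface_noise_sigma`, clipped to `[0, 255]`.
#'
#' @param config A [scene_config()]; usually from [class_preset()].
#' @param label Optional class label to attach (set automatically when the
#'   config came from [class_preset()] via [generate_dataset()]).
#' @return A [frame_sequence()] with `label`, `config` and per-frame splash
#'   ground truth in `$meta$splashes` (a list of data frames with columns
#'   `y`, `x`, `r`).
#' @export
generate_sequence <- function(config, label = NA_character_) {
  if (!inherits(config, "scene_config")) {
    abort("`config` must be a `scene_config`.", class = "feedstream_bad_config")
  }
  h <- config$frame_size[1]; w <- config$frame_size[2]
  withr::with_seed(config$seed, {
    n_fish <- config$n_fish
    fy <- runif(n_fish, 1, h); fx <- runif(n_fish, 1, w)
    heading <- runif(n_fish, 0, 2 * pi)
    # fish body axes scale mildly with frame size
    rx <- pmax(2, round(min(h, w) / 16))
    ry <- max(1, round(rx / 2))
    splashes <- list()   # active: data.frame(y, x, r, life)
    frames <- vector("list", config$n_frames)
    splash_truth <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      if (t > 1L && config$motion_scale > 0) {
        heading <- heading + rnorm(n_fish, 0, 0.35)
        step <- config$motion_scale
        fy <- fy + step * sin(heading) + rnorm(n_fish, 0, 0.25 * step)
        fx <- fx + step * cos(heading) + rnorm(n_fish, 0, 0.25 * step)
        # reflect at borders
        fy <- abs(fy - 1) %% (2 * (h - 1)) + 1
        fy <- ifelse(fy > h, 2 * h - fy, fy)
        fx <- abs(fx - 1) %% (2 * (w - 1)) + 1
        fx <- ifelse(fx > w, 2 * w - fx, fx)
      }
      if (config$splash_rate > 0) {
        k <- rpois(1L, config$splash_rate)
        if (k > 0) {
          born <- data.frame(
            y = runif(k, 1, h), x = runif(k, 1, w),
            r = pmax(1, round(config$splash_radius * runif(k, 0.7, 1.3))),
            life = sample(2:4, k, replace = TRUE),
            value = runif(k, 250, 255)
          )
          splashes <- c(splashes, split(born, seq_len(k)))
        }
      }
      canvas <- matrix(config$background_level, h, w)
      for (i in seq_len(n_fish)) {
        canvas <- draw_ellipse(canvas, fy[i], fx[i], ry, rx, heading[i], 45)
      }
      live <- Filter(function(s) s$life > 0, splashes)
      for (s in live) {
        canvas <- draw_disk(canvas, s$y, s$x, s$r, s$value)
      }
      splash_truth[[t]] <- if (length(live)) {
        do.call(rbind, lapply(live, function(s) s[c("y", "x", "r")]))
      } else {
        data.frame(y = numeric(), x = numeric(), r = numeric())
      }
      splashes <- Filter(
        function(s) s$life > 0,
        lapply(splashes, function(s) { s$life <- s$life - 1L; s })
      )
      if (config$surface_noise_sigma > 0) {
        canvas <- canvas + matrix(rnorm(h * w, 0, config$surface_noise_sigma), h, w)
      }
      frames[[t]] <- gray_to_rgb(round(clamp(canvas, 0, 255)))
    }
    frame_sequence(frames, fps = config$fps,
                   source_id = sprintf("synth_%s_%d",
                                       ifelse(is.na(label), "scene", label),
                                       config$seed),
                   label = label, config = config,
                   meta = list(splashes = splash_truth))
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' Produces `3 * n_per_class` sequences, `n_per_class` per feeding class, with
#' per-sequence seeds derived deterministically from `seed` so the dataset is
#' reproducible and independent of generation order.
#'
#' @param n_per_class Sequences per class (>= 1).
#' @param seed Master integer seed.
#' @param ... Scene overrides forwarded to [class_preset()] (e.g.
#'   `frame_size`, `n_frames`).
#' @return A list of labeled [frame_sequence()] objects, ordered
#'   none/weak/strong within each replicate index.
#' @export
generate_dataset <- function(n_per_class, seed = 1L, ...) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    abort("`n_per_class` must be >= 1.", class = "feedstream_bad_config")
  }
  n_per_class <- as.integer(n_per_class)
  out <- vector("list", 3L * n_per_class)
  k <- 0L
  for (i in seq_len(n_per_class)) {
    for (ci in seq_along(feeding_classes)) {
      k <- k + 1L
      lab <- feeding_classes[ci]
      cfg <- class_preset(lab, ..., seed = derive_seed(seed, i, salt = ci))
      seq_i <- generate_sequence(cfg, label = lab)
      seq_i$source_id <- sprintf("synth_%s_%03d", lab, i)
      out[[k]] <- seq_i
    }
  }
  out
}

#' Mean absolute inter-frame pixel difference
#'
#' Diagnostic motion-energy statistic of a sequence: the mean over consecutive
#' frame pairs of the mean absolute per-pixel gray-level difference.
#'
#' @param seq A [frame_sequence()].
#' @return A single number (gray levels/frame).
#' @export
interframe_difference <- function(seq) {
  g <- lapply(seq$frames, as_gray)
  mean(vapply(seq_len(length(g) - 1L),
              function(i) mean(abs(g[[i + 1L]] - g[[i]])), numeric(1)))
}
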