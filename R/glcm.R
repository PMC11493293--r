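# Statistical stream: gray-level co-occurrence matrices and the
# energy/entropy/contrast/correlation descriptor. At the default
# configuration (8 gray levels, offset distance 10, four angles) the
# descriptor has 16 values, ordered angle-major (0, 45, 90, 135 degrees) with
# energy, entropy, contrast, correlation within each angle.

#' GLCM configuration
#'
#' @param levels Number of quantized gray levels (>= 2; default 8).
#' @param distance Pixel offset distance `d` (>= 1; default 10).
#' @param angles Offset angles in degrees, a non-empty subset of
#'   `c(0, 45, 90, 135)`.
#' @param symmetric If `TRUE`, pair counts of the reversed offset are added so
#'   `P` equals its transpose. Default `FALSE`: the co-occurrence count is
#'   one-directional.
#' @param log_base Base of the entropy logarithm: `2` (bits, default) or
#'   `exp(1)` (nats).
#' @return A `glcm_config` object.
#' @export
glcm_config <- function(levels = 8L, distance = 10L, angles = c(0, 45, 90, 135),
                        symmetric = FALSE, log_base = 2) {
  if (levels < 2) abort("`levels` must be >= 2.", class = "feedstream_bad_config")
  if (distance < 1) abort("`distance` must be >= 1.", class = "feedstream_bad_config")
  if (!length(angles) || !all(angles %in% c(0, 45, 90, 135))) {
    abort("`angles` must be a non-empty subset of {0, 45, 90, 135}.",
          class = "feedstream_bad_config")
  }
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles = angles, symmetric = isTRUE(symmetric),
                 log_base = log_base),
            class = "glcm_config")
}

#' Quantize a grayscale image into discrete levels
#'
#' Uniform binning of the 8-bit range: `q = floor(gray * levels / 256)`, so
#' gray 0 maps to level 0 and gray 255 to `levels - 1`.
#'
#' @param image Grayscale matrix (or RGB array) with values in `[0, 255]`.
#' @param levels Number of levels (>= 2).
#' @return Integer matrix with values in `0 .. levels - 1`.
#' @export
quantize_gray <- function(image, levels = 8L) {
  if (levels < 2) abort("`levels` must be >= 2.", class = "feedstream_bad_config")
  g <- as_gray(image)
  q <- floor(g * levels / 256)
  matrix(as.integer(pmin(q, levels - 1)), nrow(g), ncol(g))
}

# Row/column offsets (a, b) for each angle, in image-row-major coordinates
# with 45 degrees pointing up-right: pixel (x, y) pairs with (x + a, y + b).
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    abort("Angle must be one of 0, 45, 90, 135.", class = "feedstream_bad_config")
  )
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts, over all in-bounds pixel pairs, how often gray level `i` at
#' `(x, y)` co-occurs with gray level `j` at the offset position for the given
#' angle and distance, then normalizes the counts to probabilities (sum 1).
#'
#' @param qimage Quantized integer matrix from [quantize_gray()] (values
#'   `< levels`).
#' @param config A [glcm_config()].
#' @param angle One angle in degrees (0, 45, 90 or 135).
#' @return A `glcm` object: list with the `levels x levels` probability
#'   matrix `P`, `config` and `angle`.
#' @export
compute_glcm <- function(qimage, config = glcm_config(), angle = 0) {
  lv <- config$levels
  if (max(qimage) >= lv || min(qimage) < 0) {
    abort("`qimage` values must lie in 0 .. levels - 1.",
          class = "feedstream_bad_image")
  }
  off <- glcm_offset(angle, config$distance)
  a <- off[1]; b <- off[2]
  h <- nrow(qimage); w <- ncol(qimage)
  rows <- seq_len(h)[seq_len(h) + a >= 1 & seq_len(h) + a <= h]
  cols <- seq_len(w)[seq_len(w) + b >= 1 & seq_len(w) + b <= w]
  if (!length(rows) || !length(cols)) {
    abort("Image too small for the requested offset: no valid pixel pair.",
          class = "feedstream_no_pairs")
  }
  i <- qimage[rows, cols, drop = FALSE]
  j <- qimage[rows + a, cols + b, drop = FALSE]
  counts <- matrix(tabulate(i * lv + j + 1L, nbins = lv * lv),
                   lv, lv, byrow = TRUE)
  if (config$symmetric) counts <- counts + t(counts)
  structure(list(P = counts / sum(counts), config = config, angle = angle),
            class = "glcm")
}

#' Texture statistics of a co-occurrence matrix
#'
#' Computes, over the normalized probabilities `P(i, j)`:
#' energy (angular second moment) `sum P^2`; entropy `-sum P log P` (with
#' `0 log 0 := 0`); contrast `sum (i - j)^2 P`; and correlation
#' `(sum i j P - mu_x mu_y) / (sigma_x sigma_y)` with marginal means and
#' standard deviations, defined as 0 when either marginal is degenerate.
#'
#' @param glcm A `glcm` from [compute_glcm()], or a normalized probability
#'   matrix.
#' @param log_base Entropy log base; defaults to the configuration stored in
#'   `glcm` (or 2).
#' @return Named numeric vector `c(energy, entropy, contrast, correlation)`.
#' @export
glcm_statistics <- function(glcm, log_base = NULL) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  log_base <- log_base %||%
    (if (inherits(glcm, "glcm")) glcm$config$log_base else 2)
  if (abs(sum(P) - 1) > 1e-9 || any(P < 0)) {
    abort("`P` must be a normalized probability matrix.",
          class = "feedstream_bad_glcm")
  }
  lv <- nrow(P)
  idx <- seq_len(lv) - 1  # levels indexed 0 .. lv-1
  energy <- sum(P^2)
  nz <- P[P > 0]
  entropy <- -sum(nz * log(nz, base = log_base))
  dif2 <- outer(idx, idx, function(a, b) (a - b)^2)
  contrast <- sum(dif2 * P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(idx * px); muy <- sum(idx * py)
  sdx <- sqrt(sum(idx^2 * px) - mux^2); sdy <- sqrt(sum(idx^2 * py) - muy^2)
  correlation <- if (!is.finite(sdx * sdy) || sdx * sdy <= 0) 0 else {
    (sum(outer(idx, idx) * P) - mux * muy) / (sdx * sdy)
  }
  c(energy = energy, entropy = entropy, contrast = contrast,
    correlation = correlation)
}

#' GLCM feature vector of an image
#'
#' Grayscale-converts, quantizes, computes one co-occurrence matrix per
#' configured angle and concatenates the four statistics per angle
#' (angle-major order), giving `4 * length(angles)` values -- 16 at the
#' default configuration.
#'
#' @param image RGB array or grayscale matrix.
#' @param config A [glcm_config()].
#' @return Named numeric vector (e.g. `energy_0, entropy_0, ...,
#'   correlation_135`).
#' @export
glcm_features <- function(image, config = glcm_config()) {
  q <- quantize_gray(image, config$levels)
  out <- lapply(config$angles, function(ang) {
    s <- glcm_statistics(compute_glcm(q, config, ang))
    setNames(s, paste0(names(s), "_", ang))
  })
  unlist(out)
}

#' GLCM feature table for labeled sequences
#'
#' One row per frame with `source_id`, `label`, `frame` and the descriptor
#' columns; the tabular input of the statistical stream.
#'
#' @param seqs List of [frame_sequence()] objects (or a single sequence).
#' @param config A [glcm_config()].
#' @return A tibble.
#' @export
glcm_feature_table <- function(seqs, config = glcm_config()) {
  if (inherits(seqs, "frame_sequence")) seqs <- list(seqs)
  rows <- purrr::map_dfr(seqs, function(s) {
    feats <- t(vapply(s$frames, function(f) glcm_features(f, config),
                      numeric(4L * length(config$angles))))
    dplyr::bind_cols(
      tibble(source_id = s$source_id, label = s$label,
             frame = seq_along(s$frames)),
      as_tibble(feats)
    )
  })
  rows
}
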