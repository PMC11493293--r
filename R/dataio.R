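# Frame-sequence container, disk round-tripping, and stratified splitting.

#' Construct a frame sequence
#'
#' The unit of classification: an ordered stack of same-sized 8-bit RGB
#' frames with a frame rate, a source identifier and an optional feeding
#' label.
#'
#' @param frames List of `H x W x 3` numeric arrays with values in
#'   `[0, 255]` (grayscale matrices are replicated to 3 channels).
#' @param fps Frames per second.
#' @param source_id Identifier string for the clip.
#' @param label Optional class label (`none`/`weak`/`strong`) or `NA`.
#' @param config Optional [scene_config()] the sequence was rendered from.
#' @param meta Optional list of extra metadata (e.g. splash ground truth).
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, fps = 24, source_id = "seq",
                           label = NA_character_, config = NULL, meta = list()) {
  if (!is.list(frames) || length(frames) < 1L) {
    abort("`frames` must be a non-empty list of images.",
          class = "feedstream_bad_sequence")
  }
  frames <- lapply(frames, function(f) if (is.matrix(f)) gray_to_rgb(f) else f)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All frames must share one (height, width).",
          class = "feedstream_mixed_sizes")
  }
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) {
    abort("Pixel values must lie in [0, 255].", class = "feedstream_bad_sequence")
  }
  if (!is.na(label)) stopifnot_label(label)
  structure(
    list(frames = frames, fps = fps, source_id = source_id, label = label,
         config = config, meta = meta),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %s: %d frames of %dx%d @ %g fps, label: %s\n",
              x$source_id, length(x$frames), d[1], d[2], x$fps, x$label))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Write a frame sequence to a directory of PNG frames
#'
#' Frames go to `frame_00001.png, ...` and the label/config metadata to a
#' `sequence.json` sidecar, the layout [load_sequence()] reads back.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    write_frame_png(seq$frames[[i]], file.path(dir, sprintf("frame_%05d.png", i)))
  }
  sidecar <- list(source_id = seq$source_id, fps = seq$fps, label = seq$label)
  if (!is.null(seq$config)) sidecar$config <- unclass(seq$config)
  jsonlite::write_json(sidecar, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Load a frame sequence from disk
#'
#' Reads a directory of PNG frames in lexical (zero-padded) order, picking up
#' the label from a `sequence.json` sidecar when present. Container video
#' files are not decodable in this package; export clips to frame directories
#' first.
#'
#' @param path Directory containing PNG frames (and optionally
#'   `sequence.json`).
#' @param fps Frame rate to record when no sidecar provides one.
#' @return A [frame_sequence()].
#' @export
load_sequence <- function(path, fps = 24) {
  if (!file.exists(path)) {
    abort(paste0("Path does not exist: ", path), class = "feedstream_io")
  }
  if (!dir.exists(path)) {
    abort(
      paste0("Video container files are not supported; supply a directory of ",
             "PNG frames (one clip per directory, lexically ordered)."),
      class = "feedstream_io"
    )
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) {
    abort(paste0("No PNG frames found in ", path), class = "feedstream_io")
  }
  frames <- lapply(files, read_frame_png)
  label <- NA_character_
  source_id <- basename(normalizePath(path))
  sidecar <- file.path(path, "sequence.json")
  if (file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(info$label) && !is.na(info$label)) label <- info$label
    if (!is.null(info$fps)) fps <- info$fps
    if (!is.null(info$source_id)) source_id <- info$source_id
  }
  frame_sequence(frames, fps = fps, source_id = source_id, label = label)
}

#' Load every sequence under a dataset root
#'
#' @param dir Directory whose subdirectories each hold one clip as written by
#'   [write_sequence()].
#' @param fps Fallback frame rate.
#' @return List of [frame_sequence()] objects, lexical order of subdirectory
#'   names.
#' @export
load_dataset <- function(dir, fps = 24) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(subdirs)) {
    abort(paste0("No sequence subdirectories under ", dir),
          class = "feedstream_io")
  }
  lapply(subdirs, load_sequence, fps = fps)
}

#' Split specification
#'
#' @param train,test,val Partition fractions; must be positive and sum to 1.
#' @param seed Integer seed for the shuffle before assignment.
#' @param unit `"sequence"` (default; whole clips move together, so no frame
#'   of one clip can reach two partitions) or `"frame"`.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train = 0.7, test = 0.2, val = 0.1, seed = 1L,
                       unit = c("sequence", "frame")) {
  unit <- match.arg(unit)
  fr <- c(train = train, test = test, val = val)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-9) {
    abort("Fractions must be positive and sum to 1.",
          class = "feedstream_bad_config")
  }
  structure(list(fractions = fr, seed = as.integer(seed), unit = unit),
            class = "split_spec")
}

# Largest-remainder apportionment of n into quotas proportional to fractions.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  quota <- floor(exact)
  rem <- n - sum(quota)
  if (rem > 0) {
    order_idx <- order(exact - quota, decreasing = TRUE)
    quota[order_idx[seq_len(rem)]] <- quota[order_idx[seq_len(rem)]] + 1
  }
  quota
}

#' Stratified train/test/validation split
#'
#' Partitions labeled items into train/test/validation sets preserving the
#' class proportions: within each class the per-partition counts are the
#' largest-remainder rounding of `class count x fraction`, and items are
#' assigned after a seeded shuffle. Partitions are disjoint and exhaustive.
#'
#' @param items Either a data frame with columns `source_id` and `label`, or
#'   a list of labeled [frame_sequence()] objects.
#' @param spec A [split_spec()].
#' @return A tibble with columns `source_id`, `label`, `partition`
#'   (`train`/`test`/`val`), one row per item, in the input order.
#' @export
stratified_split <- function(items, spec = split_spec()) {
  if (!inherits(spec, "split_spec")) {
    abort("`spec` must be a `split_spec`.", class = "feedstream_bad_config")
  }
  if (is.data.frame(items)) {
    manifest <- tibble::as_tibble(items[, c("source_id", "label")])
  } else {
    manifest <- tibble(
      source_id = vapply(items, function(s) s$source_id, character(1)),
      label = vapply(items, function(s) s$label, character(1))
    )
  }
  if (anyNA(manifest$label)) {
    abort("Every item must be labeled.", class = "feedstream_unlabeled")
  }
  missing <- setdiff(feeding_classes, unique(manifest$label))
  if (length(missing)) {
    abort(paste0("Class absent from the data: ", paste(missing, collapse = ", ")),
          class = "feedstream_missing_class")
  }
  parts <- names(spec$fractions)
  partition <- character(nrow(manifest))
  withr::with_seed(spec$seed, {
    for (cl in unique(manifest$label)) {
      idx <- which(manifest$label == cl)
      quota <- largest_remainder(length(idx), spec$fractions)
      shuffled <- idx[sample.int(length(idx))]
      partition[shuffled] <- rep(parts, times = quota)
    }
  })
  manifest$partition <- partition
  manifest
}

#' Write a split manifest to CSV
#'
#' @param manifest Tibble from [stratified_split()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
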