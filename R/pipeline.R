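# Run configuration (YAML schema with defaults and strict key validation) and
# the end-to-end pipeline: synthesize -> extract the three feature streams ->
# split -> train three classifiers -> fuse -> evaluate.

run_config_defaults <- function() {
  list(
    seed = 7L,
    scene = list(n_per_class = 20L, frame_size = c(64L, 64L), n_frames = 10L,
                 fps = 24),
    split = list(train = 0.7, test = 0.2, val = 0.1, unit = "sequence"),
    flow = list(smoothness_weight = 15, n_iterations = 100L,
                max_magnitude = 5),
    binarize = list(mode = "dual_threshold", t_s = 60, t_v = 200),
    glcm = list(levels = 8L, distance = 10L, angles = c(0, 45, 90, 135),
                symmetric = FALSE, log_base = 2),
    backbone = list(profile = "reduced"),
    conv1d = list(input_length = 16L, dense_units = 64L),
    train = list(epochs = 20L, batch_size = 32L, learning_rate = 1e-3),
    fusion = list(method = "vote"),
    streams = c("temporal", "spatial", "glcm"),
    out_dir = NULL,
    save_images = FALSE
  )
}

# Recursive merge of user values into defaults; unknown keys are errors named
# by their dotted path.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    key <- paste(c(path, extra[1]), collapse = ".")
    abort(paste0("Unknown configuration key: `", key, "`."),
          class = "feedstream_bad_config_key")
  }
  for (nm in names(user)) {
    # single-bracket assignment so a NULL value (e.g. out_dir) keeps its slot
    defaults[nm] <- list(merge_config(defaults[[nm]], user[[nm]], c(path, nm)))
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Missing keys take their defaults; unknown keys raise an error naming the
#' offending key. An empty file yields the full default configuration. The
#' `out_dir` and `save_images` keys control artifact writing in
#' [run_pipeline()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` (nested named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file does not exist: ", path), class = "feedstream_io")
  }
  user <- yaml::read_yaml(path)
  cfg <- merge_config(run_config_defaults(), user)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config A `run_config` (or plain nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Default run configuration
#'
#' @param ... Top-level overrides (named nested lists), validated against the
#'   schema.
#' @return A `run_config`.
#' @export
run_config <- function(...) {
  structure(merge_config(run_config_defaults(), list(...)),
            class = "run_config")
}

# ---- feature extraction ----------------------------------------------------

# Per-stream training items for a set of sequences. Returns, per stream, a
# list/matrix of inputs plus the per-item label and clip id.
extract_stream_inputs <- function(seqs, cfg, streams) {
  out <- list()
  if ("temporal" %in% streams) {
    xs <- list(); labs <- c(); clips <- c()
    for (s in seqs) {
      imgs <- sequence_flow_images(
        s, smoothness_weight = cfg$flow$smoothness_weight,
        n_iterations = cfg$flow$n_iterations,
        max_magnitude = cfg$flow$max_magnitude
      )
      xs <- c(xs, imgs)
      labs <- c(labs, rep(s$label, length(imgs)))
      clips <- c(clips, rep(s$source_id, length(imgs)))
    }
    out$temporal <- list(x = xs, label = labs, clip = clips)
  }
  if ("spatial" %in% streams) {
    bcfg <- binarize_config(mode = cfg$binarize$mode, t_s = cfg$binarize$t_s,
                            t_v = cfg$binarize$t_v)
    xs <- list(); labs <- c(); clips <- c()
    for (s in seqs) {
      imgs <- lapply(s$frames, function(f) gray_to_rgb(binarize(f, bcfg)))
      xs <- c(xs, imgs)
      labs <- c(labs, rep(s$label, length(imgs)))
      clips <- c(clips, rep(s$source_id, length(imgs)))
    }
    out$spatial <- list(x = xs, label = labs, clip = clips)
  }
  if ("glcm" %in% streams) {
    gcfg <- glcm_config(levels = cfg$glcm$levels, distance = cfg$glcm$distance,
                        angles = cfg$glcm$angles,
                        symmetric = cfg$glcm$symmetric,
                        log_base = cfg$glcm$log_base)
    tab <- glcm_feature_table(seqs, gcfg)
    feat_cols <- setdiff(names(tab), c("source_id", "label", "frame"))
    out$glcm <- list(x = as.matrix(tab[, feat_cols]), label = tab$label,
                     clip = tab$source_id)
  }
  out
}

subset_stream <- function(stream_data, keep_clips) {
  keep <- stream_data$clip %in% keep_clips
  x <- if (is.matrix(stream_data$x)) {
    stream_data$x[keep, , drop = FALSE]
  } else {
    stream_data$x[keep]
  }
  list(x = x, label = stream_data$label[keep], clip = stream_data$clip[keep])
}

build_stream_model <- function(stream, cfg, seed) {
  if (stream == "glcm") {
    args <- cfg$conv1d
    args$seed <- seed
    build_conv1d_net(do.call(conv1d_config, args))
  } else {
    args <- cfg$backbone
    args$seed <- seed
    args$input_size <- c(cfg$scene$frame_size, 3L)
    build_residual_backbone(do.call(residual_config, args))
  }
}

# ---- end-to-end ------------------------------------------------------------

#' Run the full three-stream pipeline on synthetic data
#'
#' Generates a balanced labeled dataset, splits it at clip level, extracts the
#' three feature streams, trains the three classifiers, fuses the test-set
#' predictions by voting, and evaluates frame-level (per stream and fused),
#' clip-level, and the full stream-subset ablation grid. Every random draw is
#' derived from `config$seed`, so a fixed configuration reproduces the report
#' exactly.
#'
#' With `config$out_dir` set, the effective configuration, split manifest,
#' training histories, per-frame predictions and the evaluation report are
#' written under one run directory (plus per-frame feature images when
#' `save_images` is `TRUE`).
#'
#' @param config A [run_config()].
#' @param progress Print stage progress messages.
#' @return A `feeding_run`: list with `config`, `manifest`, `models`,
#'   `stream_reports`, `fused_report`, `clip_report`, `ablation`,
#'   `predictions` and `dataset`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  cfg <- config
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what) say("[%s] %s", format(round(difftime(Sys.time(), t0,
                                                               units = "secs")),
                                                width = 6), what)
  streams <- cfg$streams

  stage("synthesizing scenes")
  dataset <- generate_dataset(cfg$scene$n_per_class,
                              seed = derive_seed(cfg$seed, 1, salt = 11),
                              frame_size = cfg$scene$frame_size,
                              n_frames = cfg$scene$n_frames,
                              fps = cfg$scene$fps)

  stage("splitting clips")
  manifest <- stratified_split(
    dataset,
    split_spec(cfg$split$train, cfg$split$test, cfg$split$val,
               seed = derive_seed(cfg$seed, 2, salt = 11),
               unit = cfg$split$unit)
  )
  part_of <- setNames(manifest$partition, manifest$source_id)

  stage("extracting features")
  inputs <- extract_stream_inputs(dataset, cfg, streams)

  clips_in <- function(part) manifest$source_id[manifest$partition == part]

  models <- list()
  histories <- list()
  for (i in seq_along(streams)) {
    st <- streams[i]
    stage(paste0("training ", st, " stream"))
    tr <- subset_stream(inputs[[st]], clips_in("train"))
    va <- subset_stream(inputs[[st]], clips_in("val"))
    if (!length(va$label)) va <- list(x = NULL, label = NULL)
    model <- build_stream_model(st, cfg, seed = derive_seed(cfg$seed, i, salt = 21))
    tcfg <- train_config(epochs = cfg$train$epochs,
                         batch_size = cfg$train$batch_size,
                         learning_rate = cfg$train$learning_rate,
                         seed = derive_seed(cfg$seed, i, salt = 31))
    models[[st]] <- train_stream(model, tr$x, tr$label, tcfg,
                                 x_val = va$x, labels_val = va$label)
    histories[[st]] <- models[[st]]$history
  }

  stage("evaluating on the held-out test clips")
  test_clips <- clips_in("test")
  # temporal items are frame pairs; evaluate fusion on the frame-pair grid of
  # the temporal stream aligned with the matching frames of the other streams
  stream_scores <- list()
  stream_truth <- list()
  stream_clip <- list()
  for (st in streams) {
    te <- subset_stream(inputs[[st]], test_clips)
    pred <- predict_stream(models[[st]], te$x)
    stream_scores[[st]] <- as.matrix(pred[, paste0("p_", feeding_classes)])
    stream_truth[[st]] <- te$label
    stream_clip[[st]] <- te$clip
  }
  stream_reports <- lapply(streams, function(st) {
    pred_lab <- feeding_classes[max.col(stream_scores[[st]],
                                        ties.method = "first")]
    compute_metrics(confusion_matrix(stream_truth[[st]], pred_lab))
  })
  names(stream_reports) <- streams

  # align streams on a common per-frame grid for fusion: drop each clip's
  # final frame for frame-indexed streams so counts match the pair-indexed
  # temporal stream
  aligned <- align_stream_items(stream_scores, stream_truth, stream_clip)
  fused <- fuse_batch(aligned$scores, method = cfg$fusion$method)
  fused_report <- compute_metrics(confusion_matrix(aligned$truth, fused$label))

  clip_pred <- tapply(fused$label, aligned$clip, aggregate_clip)
  clip_truth <- tapply(aligned$truth, aligned$clip, function(l) l[1])
  clip_report <- compute_metrics(
    confusion_matrix(as.character(clip_truth), as.character(clip_pred))
  )

  stage("ablation grid")
  ablation <- run_ablation(aligned$scores, aligned$truth,
                           fusion_method = cfg$fusion$method)

  predictions <- tibble(
    clip = aligned$clip, true = aligned$truth, tie_broken = fused$tie_broken,
    fused = fused$label
  )
  for (st in names(aligned$scores)) {
    predictions[[paste0(st, "_pred")]] <-
      feeding_classes[max.col(aligned$scores[[st]], ties.method = "first")]
  }

  run <- structure(list(
    config = cfg, manifest = manifest, models = models,
    histories = histories, stream_reports = stream_reports,
    fused_report = fused_report, clip_report = clip_report,
    ablation = ablation, predictions = predictions, dataset = dataset
  ), class = "feeding_run")

  if (!is.null(cfg$out_dir)) {
    stage("writing artifacts")
    write_run_artifacts(run, cfg$out_dir, save_images = isTRUE(cfg$save_images))
  }
  stage("done")
  run
}

# Align per-stream item grids for fusion. The temporal stream has one item
# per consecutive frame pair (n-1 per clip); frame-indexed streams drop each
# clip's last frame to match. Assumes items are ordered by clip and frame,
# which extract_stream_inputs guarantees.
align_stream_items <- function(stream_scores, stream_truth, stream_clip) {
  streams <- names(stream_scores)
  if (!"temporal" %in% streams || length(streams) == 1L) {
    return(list(scores = stream_scores, truth = stream_truth[[1]],
                clip = stream_clip[[1]]))
  }
  ref <- "temporal"
  keep_of <- function(st) {
    clips <- stream_clip[[st]]
    if (st == ref) return(seq_along(clips))
    unlist(lapply(split(seq_along(clips), clips), function(ix) {
      ix[-length(ix)]
    }), use.names = FALSE)
  }
  scores <- list()
  for (st in streams) {
    k <- sort(keep_of(st))
    scores[[st]] <- stream_scores[[st]][k, , drop = FALSE]
  }
  list(scores = scores,
       truth = stream_truth[[ref]],
       clip = stream_clip[[ref]])
}

write_run_artifacts <- function(run, out_dir, save_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(run$config, file.path(out_dir, "config.yaml"))
  write_manifest(run$manifest, file.path(out_dir, "split_manifest.csv"))
  for (st in names(run$histories)) {
    utils::write.csv(run$histories[[st]],
                     file.path(out_dir, paste0("history_", st, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(run$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  report <- list(
    fused = report_to_list(run$fused_report),
    clip = report_to_list(run$clip_report),
    streams = lapply(run$stream_reports, report_to_list),
    ablation = run$ablation[, c("combination", "n_streams", "accuracy",
                                "macro_f1")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (save_images) {
    img_dir <- file.path(out_dir, "frames")
    for (s in run$dataset) {
      write_sequence(s, file.path(img_dir, s$source_id))
    }
  }
  invisible(out_dir)
}

report_to_list <- function(rep) {
  list(n = rep$n, accuracy = rep$accuracy,
       macro_precision = rep$macro_precision, macro_recall = rep$macro_recall,
       macro_f1 = rep$macro_f1,
       confusion = unname(apply(rep$confusion, 1, as.integer, simplify = FALSE)),
       per_class = rep$per_class)
}

#' @export
print.feeding_run <- function(x, ...) {
  cat("<feeding_run>\n")
  for (st in names(x$stream_reports)) {
    cat(sprintf("  %-9s accuracy: %.1f%%\n", st,
                100 * x$stream_reports[[st]]$accuracy))
  }
  cat(sprintf("  fused     accuracy: %.1f%% (frame), %.1f%% (clip)\n",
              100 * x$fused_report$accuracy, 100 * x$clip_report$accuracy))
  invisible(x)
}

#' @export
glance.feeding_run <- function(x, ...) {
  out <- tibble(
    fused_accuracy = x$fused_report$accuracy,
    fused_macro_f1 = x$fused_report$macro_f1,
    clip_accuracy = x$clip_report$accuracy,
    n_test_items = x$fused_report$n
  )
  for (st in names(x$stream_reports)) {
    out[[paste0(st, "_accuracy")]] <- x$stream_reports[[st]]$accuracy
  }
  out
}

#' @export
tidy.feeding_run <- function(x, ...) x$ablation[, c("combination", "n_streams",
                                                    "accuracy", "macro_f1")]
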