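# Decision-level fusion of the three streams and the evaluation metrics:
# confusion matrix, accuracy, per-class and macro precision/recall/F1, the
# stream-subset ablation grid, and frame-to-clip aggregation.

#' Fuse three stream predictions
#'
#' Majority vote over the three streams' argmax labels. When all three
#' disagree (no majority), the tie is broken by the largest summed score
#' across streams, with exact score ties resolved to the earlier class in
#' none/weak/strong order. `method = "score_sum"` skips voting and takes the
#' argmax of the summed scores directly.
#'
#' @param preds Exactly three stream predictions: a list of length-3 score
#'   vectors (ordered none, weak, strong), a 3x3 matrix with one row per
#'   stream, or a list of one-row tibbles from [predict_stream()].
#' @param method `"vote"` (default) or `"score_sum"`.
#' @return A `fusion_result`: list with `label`, `votes` (per-stream argmax
#'   labels), `score_sums` (summed score triple) and `tie_broken` (`TRUE`
#'   when the label did not come from a strict majority).
#' @export
fuse <- function(preds, method = c("vote", "score_sum")) {
  method <- match.arg(method)
  scores <- as_score_matrix(preds)
  if (nrow(scores) != 3L) {
    abort("Exactly 3 stream predictions are required.",
          class = "feedstream_bad_fusion")
  }
  votes <- feeding_classes[max.col(scores, ties.method = "first")]
  sums <- colSums(scores)
  score_label <- feeding_classes[which.max(sums)]
  if (method == "score_sum") {
    counts <- table(factor(votes, levels = feeding_classes))
    return(structure(list(label = score_label, votes = votes,
                          score_sums = sums, tie_broken = max(counts) < 2L),
                     class = "fusion_result"))
  }
  counts <- table(factor(votes, levels = feeding_classes))
  if (max(counts) >= 2L) {
    label <- names(counts)[which.max(counts)]
    tie_broken <- FALSE
  } else {
    label <- score_label
    tie_broken <- TRUE
  }
  structure(list(label = label, votes = votes, score_sums = sums,
                 tie_broken = tie_broken),
            class = "fusion_result")
}

as_score_matrix <- function(preds) {
  if (is.matrix(preds)) return(preds)
  if (is.list(preds)) {
    rows <- lapply(preds, function(p) {
      if (is.data.frame(p)) as.numeric(p[1, paste0("p_", feeding_classes)])
      else as.numeric(p)
    })
    return(do.call(rbind, rows))
  }
  abort("`preds` must be a matrix or list of score triples.",
        class = "feedstream_bad_fusion")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s (votes: %s%s)\n", x$label,
              paste(x$votes, collapse = ", "),
              if (x$tie_broken) "; tie broken by summed score" else ""))
  invisible(x)
}

# Vectorized fusion over N items; scores: named list of N x 3 matrices.
fuse_batch <- function(stream_scores, method = c("vote", "score_sum")) {
  method <- match.arg(method)
  mats <- lapply(stream_scores, function(m) {
    m <- as.matrix(m)
    colnames(m) <- NULL
    m
  })
  n <- nrow(mats[[1]])
  summed <- Reduce(`+`, mats)
  score_label <- feeding_classes[max.col(summed, ties.method = "first")]
  if (method == "score_sum" || length(mats) != 3L) {
    return(tibble(label = score_label, tie_broken = rep(NA, n)))
  }
  votes <- vapply(mats, function(m) max.col(m, ties.method = "first"),
                  integer(n))
  votes <- matrix(votes, nrow = n)
  counts <- vapply(1:3, function(k) rowSums(votes == k), numeric(n))
  counts <- matrix(counts, nrow = n)
  has_majority <- apply(counts, 1, max) >= 2
  label <- ifelse(has_majority,
                  feeding_classes[max.col(counts, ties.method = "first")],
                  score_label)
  tibble(label = label, tie_broken = !has_majority)
}

#' Aggregate frame labels to a clip label
#'
#' Plurality over the frame decisions; ties resolve toward the stronger class
#' (strong > weak > none) -- a conservative policy for feeding control, which
#' prefers not to under-read feeding demand.
#'
#' @param frame_labels Character vector of per-frame labels.
#' @return A single label.
#' @export
aggregate_clip <- function(frame_labels) {
  if (!length(frame_labels)) {
    abort("At least one frame label is required.", class = "feedstream_bad_label")
  }
  counts <- table(factor(frame_labels, levels = feeding_classes))
  best <- which(counts == max(counts))
  feeding_classes[max(best)]   # strongest among tied classes
}

#' Confusion matrix over the three feeding classes
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @return 3x3 integer matrix, rows = true class, columns = predicted class,
#'   in none/weak/strong order.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("Label vectors must have equal length.",
          class = "feedstream_shape_mismatch")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), feeding_classes)
  if (length(bad)) {
    abort(paste0("Unknown labels: ", paste(bad, collapse = ", ")),
          class = "feedstream_bad_label")
  }
  as.matrix(table(
    factor(true_labels, levels = feeding_classes),
    factor(predicted_labels, levels = feeding_classes)
  ))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest counts per class c: TP is the diagonal entry, FN the rest of
#' row c, FP the rest of column c, TN the remainder. Accuracy is
#' `(TP + TN) / (TP + FN + FP + TN)` of the pooled decisions, i.e. the trace
#' over the total; precision `TP / (TP + FP)`; recall `TP / (TP + FN)`;
#' F1 the harmonic mean of precision and recall. Macro values are unweighted
#' class means (classes with zero support are excluded with a warning);
#' micro values pool the per-class counts, so micro-precision equals
#' micro-recall equals accuracy for single-label classification.
#'
#' @param confusion Square non-negative integer matrix (rows true, columns
#'   predicted).
#' @param averaging Reported `averaging` field of the summary: `"macro"`
#'   (default) or `"micro"`. Both sets of values are always computed.
#' @return A `metrics_report`: list with `confusion`, `accuracy`, `per_class`
#'   tibble, `macro_precision`/`macro_recall`/`macro_f1`, `micro_*`, `n`.
#' @export
compute_metrics <- function(confusion, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0)) {
    abort("`confusion` must be a square non-negative matrix.",
          class = "feedstream_bad_config")
  }
  n <- sum(confusion)
  if (n == 0) {
    abort("Confusion matrix is all zero.", class = "feedstream_bad_config")
  }
  classes <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  tp <- unname(diag(confusion))
  fn <- unname(rowSums(confusion)) - tp
  fp <- unname(colSums(confusion)) - tp
  tn <- n - tp - fn - fp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  support <- rowSums(confusion)
  per_class <- tibble(
    class = classes, support = as.integer(support),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    tn = as.integer(tn),
    precision = precision, recall = recall, f1 = f1
  )
  in_macro <- support > 0
  if (any(!in_macro)) {
    warn(paste0("Classes with zero support excluded from macro averages: ",
                paste(classes[!in_macro], collapse = ", ")))
  }
  macro <- function(v) mean(v[in_macro], na.rm = TRUE)
  micro_precision <- sum(tp) / sum(tp + fp)
  micro_recall <- sum(tp) / sum(tp + fn)
  structure(list(
    confusion = confusion,
    n = n,
    accuracy = sum(tp) / n,
    per_class = per_class,
    macro_precision = macro(precision), macro_recall = macro(recall),
    macro_f1 = macro(f1),
    micro_precision = micro_precision, micro_recall = micro_recall,
    micro_f1 = 2 * micro_precision * micro_recall /
      (micro_precision + micro_recall),
    averaging = averaging
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.1f%%\n", x$n,
              100 * x$accuracy))
  cat(sprintf("  macro P/R/F1: %.1f%% / %.1f%% / %.1f%%\n",
              100 * x$macro_precision, 100 * x$macro_recall, 100 * x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy,
         macro_precision = x$macro_precision, macro_recall = x$macro_recall,
         macro_f1 = x$macro_f1, micro_f1 = x$micro_f1)
}

#' Plot a confusion matrix
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot heat map of the confusion matrix.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true")
}

#' Evaluate every non-empty stream combination
#'
#' The ablation grid: a single stream is its own argmax; two streams combine
#' by summed-score argmax; all three use the voting rule of [fuse()].
#'
#' @param stream_scores Named list of `N x 3` score matrices (names from
#'   `temporal`, `spatial`, `glcm`), rows aligned across streams.
#' @param true_labels Character vector of length N.
#' @param streams Streams to include in the grid.
#' @param fusion_method Method for the three-stream combination.
#' @return A tibble with one row per combination: `combination`, `n_streams`,
#'   `accuracy`, `macro_f1` and the full `report` as a list column.
#' @export
run_ablation <- function(stream_scores, true_labels,
                         streams = names(stream_scores),
                         fusion_method = "vote") {
  missing <- setdiff(streams, names(stream_scores))
  if (length(missing)) {
    abort(paste0("No scores for stream(s): ", paste(missing, collapse = ", ")),
          class = "feedstream_bad_config")
  }
  combos <- unlist(lapply(seq_along(streams), function(k) {
    utils::combn(streams, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(combos, function(cmb) {
    sel <- stream_scores[cmb]
    labels <- if (length(cmb) == 3L) {
      fuse_batch(sel, method = fusion_method)$label
    } else {
      fuse_batch(sel, method = "score_sum")$label
    }
    rep <- compute_metrics(confusion_matrix(true_labels, labels))
    tibble(combination = paste(cmb, collapse = "+"),
           n_streams = length(cmb),
           accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
           report = list(rep))
  })
  dplyr::bind_rows(rows)
}
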