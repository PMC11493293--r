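# Shared fixtures, built in code at test time.

# Smooth periodic texture: wrapped noise relaxed by repeated 5-point
# averaging, rescaled to [0, 255]. Smooth enough that the linearized
# brightness-constancy constraint holds over shifts of a few pixels, with
# wrap-around consistency for circular shifts.
make_texture <- function(seed, n = 64, smooth_iters = 30) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * n), n, n)
    for (i in seq_len(smooth_iters)) {
      m <- (m +
              m[c(2:n, 1), ] + m[c(n, 1:(n - 1)), ] +
              m[, c(2:n, 1)] + m[, c(n, 1:(n - 1))]) / 5
    }
    (m - min(m)) / (max(m) - min(m)) * 255
  })
}

# Circular shift: content moves down by dy and right by dx.
shift_wrap <- function(m, dy, dx) {
  n <- nrow(m); w <- ncol(m)
  m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# The 4x4 blocks image whose horizontal d=1 co-occurrences are countable by
# hand: 12 pairs, 6 distinct (i, j) cells with 2 counts each.
blocks_image <- function() {
  matrix(c(0, 0, 1, 1,
           0, 0, 1, 1,
           2, 2, 3, 3,
           2, 2, 3, 3), 4, 4, byrow = TRUE)
}

# Direct O(H*W) double-loop pair counter; the independent oracle for
# compute_glcm.
glcm_oracle <- function(qimage, levels, d, angle, symmetric = FALSE) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (x in seq_len(nrow(qimage))) {
    for (y in seq_len(ncol(qimage))) {
      xa <- x + off[1]; yb <- y + off[2]
      if (xa >= 1 && xa <= nrow(qimage) && yb >= 1 && yb <= ncol(qimage)) {
        i <- qimage[x, y]; j <- qimage[xa, yb]
        counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
        if (symmetric) counts[j + 1, i + 1] <- counts[j + 1, i + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# Small labeled dataset used by several suites (cheap: 48x48, 5 frames).
tiny_dataset <- function(n_per_class = 2, seed = 42, frame_size = c(48, 48),
                         n_frames = 5) {
  generate_dataset(n_per_class, seed = seed, frame_size = frame_size,
                   n_frames = n_frames)
}

# Small deterministic RGB test image (gradient + bright patch).
gray_to_rgb_fixture <- function(n = 32) {
  g <- matrix(rep(seq(0, 200, length.out = n), n), n, n)
  g[5:10, 5:10] <- 250
  array(rep(g, 3), dim = c(n, n, 3))
}

# Deterministic per-item metrics oracle for compute_metrics.
metrics_oracle <- function(true, pred, classes = feeding_classes) {
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(true == cl & pred == cl)
    fp[cl] <- sum(true != cl & pred == cl)
    fn[cl] <- sum(true == cl & pred != cl)
  }
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- 2 * prec * rec / (prec + rec)
  present <- vapply(classes, function(cl) any(true == cl), logical(1))
  list(accuracy = mean(true == pred),
       macro_precision = mean(prec[present], na.rm = TRUE),
       macro_recall = mean(rec[present], na.rm = TRUE),
       macro_f1 = mean(f1[present], na.rm = TRUE))
}
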