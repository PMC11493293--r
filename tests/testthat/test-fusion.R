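score_for <- function(label, p = 0.8) {
  s <- rep((1 - p) / 2, 3)
  s[match(label, feeding_classes)] <- p
  s
}

test_that("voting fusion follows majority and summed-score tie-breaking", {
  # strict majority
  r <- fuse(list(score_for("strong"), score_for("strong"), score_for("weak")))
  expect_identical(r$label, "strong")
  expect_false(r$tie_broken)
  # unanimity
  r2 <- fuse(list(score_for("none"), score_for("none"), score_for("none")))
  expect_identical(r2$label, "none")
  expect_false(r2$tie_broken)
  # three-way disagreement: summed score decides (hand-summed example)
  preds <- rbind(c(0.5, 0.3, 0.2),    # argmax none
                 c(0.1, 0.6, 0.3),    # argmax weak
                 c(0.3, 0.3, 0.4))    # argmax strong
  expect_equal(colSums(preds), c(0.9, 1.2, 0.9))
  r3 <- fuse(preds)
  expect_identical(r3$label, "weak")
  expect_true(r3$tie_broken)
  expect_error(fuse(list(score_for("none"), score_for("weak"))),
               class = "feedstream_bad_fusion")
})

test_that("voting matches exhaustive evaluation over all 27 argmax triples", {
  # brute-force oracle: for each argmax combination, the voting rule spelled
  # out independently (count labels; majority, else largest summed score)
  for (a in 1:3) {
    for (b in 1:3) {
      for (cc in 1:3) {
        preds <- rbind(score_for(feeding_classes[a]),
                       score_for(feeding_classes[b], p = 0.7),
                       score_for(feeding_classes[cc], p = 0.6))
        counts <- tabulate(c(a, b, cc), 3)
        want <- if (max(counts) >= 2) {
          feeding_classes[which.max(counts)]
        } else {
          feeding_classes[which.max(colSums(preds))]
        }
        got <- fuse(preds)
        expect_identical(got$label, want,
                         label = sprintf("triple (%d,%d,%d)", a, b, cc))
        expect_identical(got$tie_broken, max(counts) < 2)
      }
    }
  }
})

test_that("batch fusion agrees with per-item fusion", {
  set.seed(4)
  n <- 60
  mats <- lapply(1:3, function(i) {
    m <- matrix(stats::rexp(n * 3), n, 3)
    m / rowSums(m)
  })
  names(mats) <- c("temporal", "spatial", "glcm")
  batch <- fuse_batch(mats)
  for (i in seq_len(n)) {
    single <- fuse(rbind(mats[[1]][i, ], mats[[2]][i, ], mats[[3]][i, ]))
    expect_identical(batch$label[i], single$label)
    expect_identical(batch$tie_broken[i], single$tie_broken)
  }
})

test_that("score-sum fusion takes the argmax of summed scores", {
  preds <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3), c(0.3, 0.3, 0.4))
  expect_identical(fuse(preds, method = "score_sum")$label, "weak")
})

test_that("clip aggregation is plurality with ties toward the stronger class", {
  expect_identical(aggregate_clip(rep("strong", 10)), "strong")
  expect_identical(aggregate_clip(c(rep("weak", 5), rep("strong", 5))), "strong")
  expect_identical(aggregate_clip(c(rep("none", 6), rep("weak", 4))), "none")
  expect_identical(aggregate_clip(c("none", "strong")), "strong")
  expect_error(aggregate_clip(character()), class = "feedstream_bad_label")
})

test_that("confusion matrix counts true rows against predicted columns", {
  perfect <- confusion_matrix(feeding_classes, feeding_classes)
  expect_equal(unname(diag(perfect)), rep(1L, 3), ignore_attr = TRUE)
  expect_equal(sum(perfect), 3)

  one <- confusion_matrix("none", "weak")
  expect_equal(one["none", "weak"], 1, ignore_attr = TRUE)
  expect_equal(sum(one), 1)

  set.seed(1)
  t <- sample(feeding_classes, 50, replace = TRUE)
  p <- sample(feeding_classes, 50, replace = TRUE)
  expect_equal(sum(confusion_matrix(t, p)), 50)
  expect_error(confusion_matrix(t, p[-1]), class = "feedstream_shape_mismatch")
  expect_error(confusion_matrix("none", "meh"), class = "feedstream_bad_label")
})

test_that("metrics reproduce the hand-computed one-vs-rest example", {
  # binary layout with TP=8, FP=2, FN=1, TN=9 for the first class
  conf <- matrix(c(8, 1, 2, 9), 2, 2, byrow = TRUE,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- compute_metrics(conf)
  expect_equal(100 * rep$accuracy, 85.0)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$tp, 8L)
  expect_equal(pos$fp, 2L)
  expect_equal(pos$fn, 1L)
  expect_equal(pos$tn, 9L)
  expect_equal(100 * pos$recall, 88.9, tolerance = 1e-3)
  expect_equal(100 * pos$precision, 80.0)
  expect_equal(pos$f1, 0.842, tolerance = 1e-3)
})

test_that("metrics identities hold and match a per-item oracle", {
  set.seed(6)
  for (rep_i in 1:100) {
    n <- sample(5:40, 1)
    t <- sample(feeding_classes, n, replace = TRUE)
    p <- sample(feeding_classes, n, replace = TRUE)
    if (length(unique(t)) < 3) next   # zero-support warning tested separately
    m <- compute_metrics(confusion_matrix(t, p))
    o <- metrics_oracle(t, p)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$macro_precision, o$macro_precision)
    expect_equal(m$macro_recall, o$macro_recall)
    expect_equal(m$macro_f1, o$macro_f1)
    # micro identities for single-label multiclass
    expect_equal(m$micro_precision, m$accuracy)
    expect_equal(m$micro_recall, m$accuracy)
    # per-class count conservation
    expect_true(all(m$per_class$tp + m$per_class$fp + m$per_class$fn +
                      m$per_class$tn == m$n))
  }
})

test_that("identity confusion gives perfect metrics; degenerate inputs error or warn", {
  conf <- diag(c(10L, 20L, 5L))
  dimnames(conf) <- list(feeding_classes, feeding_classes)
  m <- compute_metrics(conf)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$f1 == 1))

  expect_error(compute_metrics(matrix(0L, 3, 3)), class = "feedstream_bad_config")

  # a class never true and never predicted is excluded from macro with warning
  conf2 <- matrix(c(5L, 1L, 0L, 2L, 6L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE,
                  dimnames = list(feeding_classes, feeding_classes))
  expect_warning(m2 <- compute_metrics(conf2), "zero support")
  o <- metrics_oracle(rep(c("none", "weak"), c(6, 8)),
                      rep(c("none", "weak", "none", "weak"), c(5, 1, 2, 6)))
  expect_equal(m2$macro_recall, o$macro_recall)
})

test_that("the ablation grid covers all seven subsets with correct composition", {
  set.seed(2)
  n <- 45
  truth <- sample(feeding_classes, n, replace = TRUE)
  mk <- function(acc) {
    t(vapply(seq_len(n), function(i) {
      lab <- if (stats::runif(1) < acc) truth[i] else sample(setdiff(feeding_classes, truth[i]), 1)
      score_for(lab)
    }, numeric(3)))
  }
  scores <- list(temporal = mk(0.9), spatial = mk(0.8), glcm = mk(0.7))
  grid <- run_ablation(scores, truth)
  expect_equal(nrow(grid), 7)
  expect_setequal(grid$n_streams, c(1, 1, 1, 2, 2, 2, 3))
  # singleton rows equal the stream's standalone metrics
  solo <- compute_metrics(confusion_matrix(
    truth, feeding_classes[max.col(scores$glcm, ties.method = "first")]
  ))
  expect_equal(grid$accuracy[grid$combination == "glcm"], solo$accuracy)
  expect_error(run_ablation(scores, truth, streams = c("temporal", "lidar")),
               class = "feedstream_bad_config")
})
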