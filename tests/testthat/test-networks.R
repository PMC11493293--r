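test_that("backbone structural counts follow the closed-form formulas", {
  full <- build_residual_backbone(residual_config("full"))
  expect_identical(full$summary$conv_layers, 49L)
  expect_identical(full$summary$weighted_layers, 50L)
  expect_equal(full$summary$prepool_shape, c(7, 7, 2048))

  tiny <- build_residual_backbone(residual_config("reduced"))
  expect_identical(tiny$summary$conv_layers, 13L)   # 1 + 3 x 4
  expect_equal(tiny$summary$prepool_shape[3], 256)

  odd <- build_residual_backbone(
    residual_config("full", stage_blocks = c(2, 2, 2, 2))
  )
  expect_identical(odd$summary$conv_layers, 1L + 3L * 8L)

  basic <- build_residual_backbone(
    residual_config("reduced", bottleneck = FALSE)
  )
  expect_identical(basic$summary$conv_layers, 1L + 2L * 4L)

  expect_error(residual_config("full", stage_blocks = c(0, 1, 1, 1)),
               class = "feedstream_bad_config")
  expect_error(residual_config("full", n_classes = 1),
               class = "feedstream_bad_config")
})

test_that("classifier outputs are normalized score distributions", {
  m <- build_conv1d_net(conv1d_config(seed = 5))
  x <- matrix(rnorm(7 * 16), 7, 16)
  p <- predict_stream(m, x)
  expect_equal(nrow(p), 7)
  scores <- as.matrix(p[, c("p_none", "p_weak", "p_strong")])
  expect_true(all(scores >= 0))
  expect_equal(rowSums(scores), rep(1, 7), tolerance = 1e-6)
  # argmax column consistent with scores
  expect_identical(p$.pred_class,
                   feeding_classes[max.col(scores, ties.method = "first")])
  # duplicated input -> identical rows; repeated forward -> identical output
  x2 <- x[c(1, 1, 2), ]
  p2 <- predict_stream(m, x2)
  expect_equal(p2[1, ], p2[2, ])
  expect_identical(predict_stream(m, x), p)
})

test_that("1D network validates kernel/pool widths against the vector length", {
  expect_error(
    build_conv1d_net(conv1d_config(input_length = 4,
                                   conv_blocks = list(c(8L, 5L, 2L)))),
    class = "feedstream_bad_config"
  )
  expect_error(build_conv1d_net(conv1d_config(conv_blocks = list())),
               class = "feedstream_bad_config")
})

test_that("training rejects degenerate requests", {
  m <- build_conv1d_net(conv1d_config(seed = 1))
  x <- matrix(rnorm(6 * 16), 6, 16)
  expect_error(train_config(epochs = 0), class = "feedstream_bad_config")
  # a class missing from the training labels
  expect_error(
    train_stream(m, x, rep(c("none", "weak"), 3), train_config(epochs = 1)),
    class = "feedstream_missing_class"
  )
  # wrong input width
  expect_error(predict_stream(m, matrix(0, 2, 8)),
               class = "feedstream_shape_mismatch")
})

test_that("the 1D net fits separable vectors and training is seed-reproducible", {
  # three well-separated Gaussian prototypes in descriptor space
  set.seed(14)
  protos <- matrix(rnorm(3 * 16, sd = 2), 3, 16)
  n_per <- 40
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rep(protos[k, ], each = n_per), n_per, 16) +
      matrix(rnorm(n_per * 16, sd = 0.2), n_per, 16)
  }))
  labs <- rep(feeding_classes, each = n_per)
  m <- build_conv1d_net(conv1d_config(seed = 2))
  tr <- train_stream(m, x, labs, train_config(epochs = 15, seed = 8))
  expect_equal(nrow(tr$history), 15)
  expect_true(all(is.finite(tr$history$train_loss)))
  expect_gte(mean(predict_stream(tr, x)$.pred_class == labs), 0.95)

  m2 <- build_conv1d_net(conv1d_config(seed = 2))
  tr2 <- train_stream(m2, x, labs, train_config(epochs = 15, seed = 8))
  expect_identical(tr$history, tr2$history)
})

test_that("a reduced 2D stream fits 20 separable clips per class", {
  # flow images are per-pair separable: calm scenes carry no motion at all,
  # weak scenes slow localized motion, strong scenes fast motion and splashes
  ds <- generate_dataset(20, seed = 31, frame_size = c(64, 64), n_frames = 3)
  xs <- list()
  labs <- character()
  for (s in ds) {
    imgs <- sequence_flow_images(s, max_magnitude = 5)
    xs <- c(xs, imgs)
    labs <- c(labs, rep(s$label, length(imgs)))
  }
  m <- build_residual_backbone(residual_config("reduced", seed = 13))
  tr <- train_stream(m, xs, labs, train_config(epochs = 10, seed = 5))
  expect_gte(mean(predict_stream(tr, xs)$.pred_class == labs), 0.95)
  expect_true(all(is.finite(tr$history$train_loss)))
  # tidy/glance accessors
  expect_identical(tidy(tr), tr$history)
  expect_equal(glance(tr)$epochs, 10)
})
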