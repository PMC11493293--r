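test_that("spatiotemporal gradients behave analytically", {
  a <- matrix(runif(30 * 40, 0, 255), 30, 40)
  g0 <- spatiotemporal_gradients(a, a)
  expect_true(all(g0$It == 0))

  # intensity ramp along X: Ix ~ 1, Iy ~ 0 at interior pixels
  ramp <- matrix(rep(seq_len(40), each = 30), 30, 40)
  g <- spatiotemporal_gradients(ramp, ramp)
  expect_equal(g$Ix[5:25, 5:35], matrix(1, 21, 31), ignore_attr = TRUE)
  expect_equal(g$Iy[5:25, 5:35], matrix(0, 21, 31), ignore_attr = TRUE)

  # uniform brightening: It constant, spatial gradients unchanged
  g10 <- spatiotemporal_gradients(a, a + 10)
  expect_equal(g10$It, matrix(10, 30, 40), ignore_attr = TRUE)
  expect_equal(g10$Ix, g0$Ix)   # constant offset drops out of central diffs
  expect_equal(g10$Iy, g0$Iy)

  expect_error(spatiotemporal_gradients(a, matrix(0, 10, 10)),
               class = "feedstream_shape_mismatch")
})

test_that("identical frames give the zero flow field", {
  tex <- make_texture(1)
  fl <- estimate_flow(tex, tex)
  expect_true(all(fl$u == 0))
  expect_true(all(fl$v == 0))
})

test_that("flow recovers known translations within half a pixel", {
  epe <- c()
  for (case in 1:10) {
    sh <- withr::with_seed(100 + case, sample(-3:3, 2, replace = TRUE))
    tex <- make_texture(case)
    fl <- estimate_flow(tex, shift_wrap(tex, sh[1], sh[2]))
    epe <- c(epe, mean(sqrt((fl$u - sh[2])^2 + (fl$v - sh[1])^2)))
    if (case == 1) {
      expect_lt(abs(median(fl$u) - sh[2]), 0.5)
      expect_lt(abs(median(fl$v) - sh[1]), 0.5)
    }
  }
  expect_lt(mean(epe), 0.5)
})

test_that("the solver's energy is non-increasing across sweeps", {
  set.seed(5)
  a <- matrix(runif(40 * 40, 0, 255), 40, 40)
  b <- matrix(runif(40 * 40, 0, 255), 40, 40)
  fl <- estimate_flow(a, b, smoothness_weight = 10, n_iterations = 50)
  en <- attr(fl, "energy")
  expect_length(en, 50)
  expect_true(all(diff(en) <= 1e-8 * max(abs(en))))
  # reported energy matches the objective evaluated in R
  expect_equal(en[50], flow_energy(fl, attr(fl, "gradients"), 10),
               tolerance = 1e-10)
})

test_that("flow estimation validates its inputs", {
  tex <- make_texture(2)
  expect_error(estimate_flow(tex, tex, smoothness_weight = 0),
               class = "feedstream_bad_config")
  bad <- tex
  bad[1, 1] <- NaN
  expect_error(estimate_flow(tex, bad), class = "feedstream_nonfinite")
})

test_that("flow rendering follows the color-wheel convention", {
  z <- list(u = matrix(0, 8, 8), v = matrix(0, 8, 8))
  img <- flow_to_image(z)
  # zero flow: one constant reference color everywhere (white)
  expect_equal(max(img) - min(img), 0)
  expect_equal(img[1, 1, ], c(255, 255, 255))

  fl1 <- list(u = matrix(1, 8, 8), v = matrix(0.5, 8, 8))
  fl2 <- list(u = matrix(2, 8, 8), v = matrix(1, 8, 8))
  i1 <- flow_to_image(fl1, max_magnitude = 4)
  i2 <- flow_to_image(fl2, max_magnitude = 4)
  hsv1 <- grDevices::rgb2hsv(i1[1, 1, 1], i1[1, 1, 2], i1[1, 1, 3], maxColorValue = 255)
  hsv2 <- grDevices::rgb2hsv(i2[1, 1, 1], i2[1, 1, 2], i2[1, 1, 3], maxColorValue = 255)
  # same direction -> same hue (up to 8-bit quantization); double magnitude
  # -> more saturated
  expect_lt(abs(hsv1["h", 1] - hsv2["h", 1]), 0.02)
  expect_gt(hsv2["s", 1], hsv1["s", 1])

  # +X and -X flows sit 180 degrees apart on the wheel
  px <- flow_to_image(list(u = matrix(1, 4, 4), v = matrix(0, 4, 4)),
                      max_magnitude = 1)
  nx <- flow_to_image(list(u = matrix(-1, 4, 4), v = matrix(0, 4, 4)),
                      max_magnitude = 1)
  hp <- grDevices::rgb2hsv(px[1, 1, 1], px[1, 1, 2], px[1, 1, 3], maxColorValue = 255)["h", 1]
  hn <- grDevices::rgb2hsv(nx[1, 1, 1], nx[1, 1, 2], nx[1, 1, 3], maxColorValue = 255)["h", 1]
  expect_equal(unname(abs(hp - hn)), 0.5, tolerance = 1e-6)
})

test_that("sequence flow images come one per consecutive frame pair", {
  s <- generate_sequence(class_preset("weak", frame_size = c(48, 48),
                                      n_frames = 4, seed = 1), label = "weak")
  imgs <- sequence_flow_images(s, n_iterations = 20)
  expect_length(imgs, 3)
  expect_equal(dim(imgs[[1]]), c(48, 48, 3))
})
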