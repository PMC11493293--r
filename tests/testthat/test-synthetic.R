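test_that("class presets realize the feeding-intensity semantics", {
  none <- class_preset("none")
  weak <- class_preset("weak")
  strong <- class_preset("strong")
  # calm water: no motion, no splash
  expect_identical(none$motion_scale, 0)
  expect_identical(none$splash_rate, 0)
  # strict ordering of the agitation parameters
  expect_true(none$motion_scale < weak$motion_scale &&
                weak$motion_scale < strong$motion_scale)
  expect_true(none$splash_rate < weak$splash_rate &&
                weak$splash_rate < strong$splash_rate)
  expect_true(none$splash_radius < weak$splash_radius &&
                weak$splash_radius < strong$splash_radius)
  # determinism of the preset itself
  expect_identical(class_preset("weak", seed = 5), class_preset("weak", seed = 5))
  expect_error(class_preset("frenzy"), class = "feedstream_bad_label")
})

test_that("scene_config validates its invariants", {
  expect_error(scene_config(frame_size = c(16, 64)), class = "feedstream_bad_config")
  expect_error(scene_config(n_frames = 1), class = "feedstream_bad_config")
  expect_error(scene_config(motion_scale = -1), class = "feedstream_bad_config")
})

test_that("generation is bit-reproducible and stochastic terms are the only difference sources", {
  cfg <- class_preset("strong", frame_size = c(48, 48), n_frames = 6, seed = 7)
  s1 <- generate_sequence(cfg, label = "strong")
  s2 <- generate_sequence(cfg, label = "strong")
  expect_identical(s1$frames, s2$frames)
  expect_length(s1$frames, 6)
  expect_equal(dim(s1$frames[[1]]), c(48, 48, 3))

  # no motion, no splash, no noise -> every frame identical
  still <- generate_sequence(scene_config(frame_size = c(48, 48), n_frames = 4,
                                          motion_scale = 0, splash_rate = 0,
                                          surface_noise_sigma = 0, seed = 1))
  for (f in still$frames) expect_identical(f, still$frames[[1]])
})

test_that("strong scenes move more than calm scenes (same seed, 200 frames)", {
  strong <- generate_sequence(class_preset("strong", frame_size = c(48, 48),
                                           n_frames = 200, seed = 11),
                              label = "strong")
  none <- generate_sequence(class_preset("none", frame_size = c(48, 48),
                                         n_frames = 200, seed = 11),
                            label = "none")
  expect_gt(interframe_difference(strong), interframe_difference(none))
})

test_that("motion energy orders none < weak < strong over a 20-seed suite", {
  for (seed in 1:20) {
    d <- vapply(feeding_classes, function(lab) {
      interframe_difference(generate_sequence(
        class_preset(lab, frame_size = c(48, 48), n_frames = 100, seed = seed),
        label = lab
      ))
    }, numeric(1))
    expect_true(d[["none"]] < d[["weak"]] && d[["weak"]] < d[["strong"]],
                label = sprintf("ordering at seed %d (%s)", seed,
                                paste(round(d, 2), collapse = " < ")))
  }
})

test_that("splashes make strong frames visibly brighter than calm frames", {
  strong <- generate_sequence(class_preset("strong", frame_size = c(64, 64),
                                           n_frames = 50, seed = 3))
  none <- generate_sequence(class_preset("none", frame_size = c(64, 64),
                                         n_frames = 50, seed = 3))
  bright_frac <- function(f) mean(as_gray(f) >= 250)
  wins <- mapply(function(a, b) bright_frac(a) > bright_frac(b),
                 strong$frames, none$frames)
  expect_gte(mean(wins), 0.95)
})

test_that("generate_dataset is balanced, labeled and reproducible", {
  ds <- generate_dataset(5, seed = 9, frame_size = c(48, 48), n_frames = 3)
  expect_length(ds, 15)
  labs <- vapply(ds, function(s) s$label, character(1))
  expect_equal(unname(table(labs)[feeding_classes]), rep(5L, 3),
               ignore_attr = TRUE)
  ds2 <- generate_dataset(5, seed = 9, frame_size = c(48, 48), n_frames = 3)
  expect_identical(lapply(ds, `[[`, "frames"), lapply(ds2, `[[`, "frames"))

  ds1 <- generate_dataset(1, seed = 2, frame_size = c(48, 48), n_frames = 3)
  expect_setequal(vapply(ds1, function(s) s$label, character(1)),
                  feeding_classes)
  expect_error(generate_dataset(0), class = "feedstream_bad_config")
})

test_that("labels attached to generated sequences match their presets", {
  ds <- tiny_dataset()
  for (s in ds) {
    expect_s3_class(s$config, "scene_config")
    expect_identical(s$config$motion_scale,
                     class_preset(s$label)$motion_scale)
    expect_identical(s$config$splash_rate, class_preset(s$label)$splash_rate)
  }
})
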