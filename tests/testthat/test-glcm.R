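test_that("gray quantization uses uniform floor binning", {
  expect_equal(quantize_gray(matrix(0, 1, 1), 8)[1, 1], 0L)
  expect_equal(quantize_gray(matrix(255, 1, 1), 8)[1, 1], 7L)
  expect_equal(quantize_gray(matrix(32, 1, 1), 8)[1, 1], 1L)
  expect_true(all(quantize_gray(matrix(128, 4, 4), 8) == 4L))
  expect_error(quantize_gray(matrix(0, 2, 2), 1), class = "feedstream_bad_config")
})

test_that("the blocks image reproduces the hand-counted co-occurrences", {
  q <- blocks_image()
  g <- compute_glcm(q, glcm_config(levels = 4, distance = 1), angle = 0)
  # 12 horizontal pairs; six distinct cells with 2 counts each
  expect_equal(sum(g$P > 0), 6)
  expect_true(all(abs(g$P[g$P > 0] - 2 / 12) < 1e-12))
  expect_equal(sum(g$P), 1)
  # the cells: (0,0),(0,1),(1,1) in the top half, (2,2),(2,3),(3,3) below
  expect_equal(g$P[1, 1], 1 / 6)
  expect_equal(g$P[1, 2], 1 / 6)
  expect_equal(g$P[3, 4], 1 / 6)
})

test_that("constant and degenerate images produce the expected matrices", {
  const <- matrix(3L, 8, 8)
  g <- compute_glcm(const, glcm_config(levels = 8, distance = 2), angle = 0)
  expect_equal(g$P[4, 4], 1)
  expect_equal(sum(g$P), 1)
  # symmetric mode gives a symmetric matrix
  set.seed(1)
  q <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  gs <- compute_glcm(q, glcm_config(levels = 4, distance = 3, symmetric = TRUE),
                     angle = 45)
  expect_equal(gs$P, t(gs$P))
  # offset larger than the image: no valid pair
  expect_error(compute_glcm(matrix(0L, 4, 4), glcm_config(levels = 2, distance = 10), 0),
               class = "feedstream_no_pairs")
})

test_that("compute_glcm matches the brute-force pair counter on random images", {
  set.seed(7)
  for (rep in 1:50) {
    q <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
    d <- sample(1:4, 1)
    for (ang in c(0, 45, 90, 135)) {
      got <- compute_glcm(q, glcm_config(levels = 8, distance = d), ang)$P
      want <- glcm_oracle(q, 8, d, ang)
      expect_equal(got, want, ignore_attr = TRUE,
                   label = sprintf("rep %d angle %d d %d", rep, ang, d))
    }
  }
})

test_that("texture statistics reproduce the closed-form examples", {
  const <- glcm_statistics(compute_glcm(matrix(0L, 6, 6),
                                        glcm_config(levels = 4, distance = 1), 0))
  expect_equal(unname(const["energy"]), 1)
  expect_equal(unname(const["entropy"]), 0)
  expect_equal(unname(const["contrast"]), 0)
  expect_equal(unname(const["correlation"]), 0)  # degenerate marginals

  blocks <- glcm_statistics(compute_glcm(blocks_image(),
                                         glcm_config(levels = 4, distance = 1), 0))
  expect_equal(unname(blocks["energy"]), 1 / 6)
  expect_equal(unname(blocks["entropy"]), log2(6))
  expect_equal(unname(blocks["contrast"]), 1 / 3)

  # uniform matrix attains the entropy maximum log2(levels^2)
  u <- matrix(1 / 16, 4, 4)
  expect_equal(unname(glcm_statistics(u)["entropy"]), log2(16))

  expect_error(glcm_statistics(matrix(1, 2, 2)), class = "feedstream_bad_glcm")
})

test_that("statistics invariants hold on random matrices", {
  set.seed(3)
  for (rep in 1:20) {
    p <- matrix(stats::rexp(64), 8, 8)
    p <- p / sum(p)
    s <- glcm_statistics(p)
    expect_lte(s[["energy"]], 1)
    expect_gt(s[["energy"]], 0)
    expect_gte(s[["entropy"]], 0)
    expect_gte(s[["contrast"]], 0)
    expect_true(s[["correlation"]] >= -1 - 1e-12 && s[["correlation"]] <= 1 + 1e-12)
  }
  # energy 1 and entropy 0 iff a single nonzero cell
  single <- matrix(0, 8, 8)
  single[2, 5] <- 1
  s <- glcm_statistics(single)
  expect_equal(s[["energy"]], 1)
  expect_equal(s[["entropy"]], 0)
  # contrast 0 iff all mass on the diagonal
  diag_p <- diag(8) / 8
  expect_equal(glcm_statistics(diag_p)[["contrast"]], 0)
})

test_that("the descriptor has 4 statistics per angle in angle-major order", {
  img <- gray_to_rgb_fixture()
  v <- glcm_features(img)
  expect_length(v, 16)
  expect_identical(names(v)[1:4],
                   c("energy_0", "entropy_0", "contrast_0", "correlation_0"))
  expect_identical(names(v)[13:16],
                   c("energy_135", "entropy_135", "contrast_135",
                     "correlation_135"))
  v0 <- glcm_features(img, glcm_config(angles = 0))
  expect_length(v0, 4)
  expect_equal(unname(v0), unname(v[1:4]))
})

test_that("0-degree features of an image equal 90-degree features of its rotation", {
  set.seed(9)
  g <- matrix(runif(30 * 30, 0, 255), 30, 30)
  # rotate 90 degrees counterclockwise: rows become reversed columns
  rot <- t(g)[ncol(g):1, ]
  f_orig <- glcm_features(g, glcm_config(levels = 8, distance = 3,
                                         angles = c(0, 90)))
  f_rot <- glcm_features(rot, glcm_config(levels = 8, distance = 3,
                                          angles = c(0, 90)))
  expect_equal(unname(f_orig[1:4]), unname(f_rot[5:8]), tolerance = 1e-12)
})

test_that("feature tables carry ids, labels and one row per frame", {
  ds <- tiny_dataset()
  tab <- glcm_feature_table(ds, glcm_config(distance = 5))
  expect_equal(nrow(tab), sum(vapply(ds, length, integer(1))))
  expect_true(all(c("source_id", "label", "frame", "energy_0") %in% names(tab)))
})

test_that("strong and calm scenes separate on 0-degree energy across 20 seeds", {
  e0 <- function(lab, seed) {
    s <- generate_sequence(class_preset(lab, frame_size = c(48, 48),
                                       n_frames = 2, seed = seed))
    glcm_features(s$frames[[1]], glcm_config(distance = 5, angles = 0))[["energy_0"]]
  }
  strong <- vapply(1:20, function(s) e0("strong", s), numeric(1))
  none <- vapply(1:20, function(s) e0("none", s), numeric(1))
  # calm water is nearly uniform -> much higher energy than splashy texture
  expect_true(all(none > strong))
})
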