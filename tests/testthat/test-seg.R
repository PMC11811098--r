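test_that("IPH is the maximum column-wise vertical extent", {
  expect_identical(compute_iph(matrix(0, 10, 10))$iph_px, 0L)
  expect_identical(compute_iph(matrix(0, 10, 10))$iph_frac, 0)

  m <- matrix(0, 600, 4); m[100:219, 2] <- 1
  r <- compute_iph(m)
  expect_identical(r$iph_px, 120L)
  expect_equal(r$iph_frac, 0.20)

  one <- matrix(0, 50, 50); one[7, 9] <- 1
  expect_identical(compute_iph(one)$iph_px, 1L)
  expect_equal(compute_iph(one)$iph_frac, 1 / 50)

  # the extent spans gaps within a column
  g <- matrix(0, 20, 3); g[c(3, 10), 1] <- 1
  expect_identical(compute_iph(g)$iph_px, 8L)

  expect_error(compute_iph(m, image_h = 0), "positive")
})

test_that("IPH is invariant under horizontal flips of the mask", {
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rbinom(30 * 40, 1, 0.2), 30, 40)
    expect_identical(compute_iph(m)$iph_px,
                     compute_iph(m[, 40:1])$iph_px)
  }
})

test_that("segmentation metrics follow their set definitions", {
  a <- matrix(0, 8, 8); a[3:6, 3:6] <- 1
  id <- evaluate_segmentation(list(a), list(a))
  expect_equal(unname(id$mean), rep(1, 4))

  b <- matrix(0, 8, 8); b[1:2, 1:2] <- 1   # disjoint from a
  dj <- evaluate_segmentation(list(b), list(a))
  expect_equal(dj$mean[["dsc"]], 0)
  expect_equal(dj$mean[["iou"]], 0)

  # prediction = left half of the truth (equal-area halves)
  h <- matrix(0, 8, 8); h[3:6, 3:4] <- 1
  hv <- evaluate_segmentation(list(h), list(a))
  expect_equal(hv$mean[["dsc"]], 2 / 3)

  # empty-vs-empty counts as perfect agreement
  z <- matrix(0, 8, 8)
  expect_equal(unname(evaluate_segmentation(list(z), list(z))$mean), rep(1, 4))

  expect_error(evaluate_segmentation(list(a), list(a, a)), "length")
})

test_that("DSC and IOU satisfy DSC = 2 IOU / (1 + IOU) frame by frame", {
  set.seed(2)
  for (i in 1:30) {
    p <- matrix(rbinom(400, 1, runif(1, 0.1, 0.6)), 20, 20)
    g <- matrix(rbinom(400, 1, runif(1, 0.1, 0.6)), 20, 20)
    m <- evaluate_segmentation(list(p), list(g))$per_frame
    expect_equal(m$dsc, 2 * m$iou / (1 + m$iou))
    expect_lte(m$iou, m$dsc)
  }
})

test_that("nearest-neighbour resize preserves binary masks through a round trip", {
  spec <- synth_spec(image_w = 160, image_h = 120)
  m <- render_frame(0.3, spec)$mask
  up <- resize_nn(m, 240, 320)
  back <- resize_nn(up, 120, 160)
  expect_identical(back, m)
})

test_that("training rejects degenerate datasets", {
  expect_error(train_segmentation(list(), list()), "empty")
  f <- matrix(0.5, 32, 32)
  expect_error(train_segmentation(list(f), list(matrix(0, 16, 16))),
               "mismatch")
  expect_error(seg_config(input_size = 100), "divisible")
  expect_error(seg_config(patience = 200, epochs = 100), "patience")
})

test_that("an untrained or foreign model handle is rejected", {
  expect_error(segment_frame(list(), matrix(0, 8, 8)), "not a trained")
  expect_error(classify_frame(list(), matrix(0, 8, 8)), "not a trained")
})
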