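test_that("the open/closed correction zeroes disappearance frames only", {
  expect_identical(correct_iph("disappearance", 37), 0)
  expect_identical(correct_iph("existence", 37), 37)
  expect_identical(correct_iph("disappearance", 0), 0)
  expect_error(correct_iph("existence", -1), ">= 0")
  expect_error(correct_iph("open", 3), "label")

  # idempotence over random vectors of labels/heights
  set.seed(1)
  for (i in 1:20) {
    lab <- sample(c("existence", "disappearance"), 15, replace = TRUE)
    iph <- sample(0:120, 15, replace = TRUE)
    once <- correct_iph(lab, iph)
    expect_identical(correct_iph(lab, once), once)
  }
})

test_that("frame-classification metrics follow confusion-matrix arithmetic", {
  perfect <- rep(c("disappearance", "existence"), c(4, 6))
  m <- evaluate_frame_classification(perfect, perfect)
  expect_equal(c(m$accuracy, m$precision, m$sensitivity, m$specificity, m$f1),
               rep(1, 5))

  # TP 9, FN 1, TN 8, FP 2
  truth <- rep(c("disappearance", "existence"), c(10, 10))
  pred <- c(rep("disappearance", 9), "existence",
            rep("disappearance", 2), rep("existence", 8))
  m2 <- evaluate_frame_classification(pred, truth)
  expect_equal(m2$sensitivity, 0.90)
  expect_equal(m2$specificity, 0.80)
  expect_equal(round(m2$precision, 4), 0.8182)
  expect_equal(m2$accuracy, 0.85)
  expect_equal(round(m2$f1, 4), 0.8571)

  expect_error(evaluate_frame_classification(character(0), character(0)),
               "empty")
})

test_that("reported F1 is always the harmonic mean of precision and sensitivity", {
  set.seed(2)
  for (i in 1:25) {
    truth <- sample(c("disappearance", "existence"), 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.8, truth,
                   sample(c("disappearance", "existence"), 40, replace = TRUE))
    m <- evaluate_frame_classification(pred, truth)
    if (!anyNA(c(m$precision, m$sensitivity)))
      expect_equal(round(m$f1, 4), round(f1_score(m$precision, m$sensitivity), 4))
  }
})

test_that("classifier correction improves on segmentation-only frame calls", {
  # fixture: spurious residual foreground injected into truly closed frames
  set.seed(3)
  truth <- rep(c("disappearance", "existence"), c(30, 70))
  iph <- c(sample(5:40, 30, replace = TRUE),   # false positives when closed
           sample(80:200, 70, replace = TRUE))
  cls <- truth                                  # a well-trained classifier
  cls[sample(100, 3)] <- "existence"            # with a few misses
  res <- compare_frame_systems(iph, cls, truth)
  expect_gt(res["segmentation_plus_classifier", "accuracy"],
            res["segmentation_only", "accuracy"])
  expect_lt(res["segmentation_only", "sensitivity"], 0.2)
  # each row's F1 is consistent with its own precision/sensitivity
  for (r in 1:2)
    if (!anyNA(res[r, c("precision", "sensitivity")]))
      expect_equal(res[r, "f1"],
                   f1_score(res[r, "precision"], res[r, "sensitivity"]))
})

test_that("training configuration validates the stage layout", {
  expect_error(cls_config(input_size = 100), "divisible")
  expect_error(cls_config(embed = 10, heads = c(3, 3, 3, 3)), "divisible")
  cfg <- cls_config(input_size = 64, patch = 4, embed = 16,
                    depths = c(1, 1, 1, 1), heads = c(2, 2, 2, 2), window = 4)
  expect_s3_class(cfg, "cls_config")
})
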