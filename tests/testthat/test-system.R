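# End-to-end behaviour with small trained models on synthetic recordings.

test_that("classifier correction improves accuracy when the segmenter
           leaves residue on closed frames", {
  cls <- tiny_cls_model()
  spec <- tiny_spec()

  set.seed(31)
  n <- 60
  iphs <- ifelse(runif(n) < 0.5, 0, runif(n, 0.1, 0.5))
  truth <- ifelse(iphs == 0, "disappearance", "existence")
  frames <- lapply(seq_len(n), function(i)
    render_frame(iphs[i], spec, seed = 600 + i)$image)

  # oracle segmentation heights with spurious foreground injected into the
  # truly closed frames (the segmentation failure mode the classifier fixes)
  iph_px <- round(iphs * spec$image_h)
  iph_px[truth == "disappearance"] <-
    sample(3:25, sum(truth == "disappearance"), replace = TRUE)

  states <- vapply(frames, function(f) classify_frame(cls, f)$state,
                   character(1))
  res <- compare_frame_systems(iph_px, states, truth)
  expect_lt(res["segmentation_only", "accuracy"],
            res["segmentation_plus_classifier", "accuracy"])
  expect_gte(res["segmentation_plus_classifier", "accuracy"], 0.9)
})

test_that("analyze_video recovers the scheduled blinks from rendered frames", {
  seg <- tiny_seg_model()
  cls <- tiny_cls_model()

  sch <- list(
    blink_event_spec(1.0, 0.30, 0.25, 0.40, 0),           # complete
    blink_event_spec(3.0, 0.30, 0, 0.40, 0.45),           # incomplete
    blink_event_spec(5.0, 0.35, 0, 0.45, 0.35)            # incomplete
  )
  spec <- synth_spec(duration_s = 7, fps = 20, image_w = 96, image_h = 72,
                     baseline_iph_frac = 0.35, events = sch,
                     pixel_noise_sd = 3, seed = 13)
  vid <- synthesize_video(spec)

  # k = 4 at 20 fps demands ramps of >= 0.2 s, the same physical threshold
  # as the default k = 5 at 30 fps (single-pixel plateaus in the segmented
  # wave would otherwise split the strict runs of slow 72-px recordings)
  an <- analyze_video(vid$frames, seg, cls, fps = 20, k = 4)
  expect_identical(an$metrics$CB, 1L)
  expect_identical(an$metrics$IB, 2L)
  expect_equal(an$metrics$IBR, 2 / 3)
  # starts and troughs track the schedule closely; ends may stop a few
  # frames early where the reopening wave plateaus within a pixel
  tr <- vid$truth$events
  expect_true(all(abs(an$events$start_f - tr$start_f) <= 2))
  expect_true(all(abs(an$events$trough_f - tr$trough_f) <= 2))
  expect_true(all(abs(an$events$end_f - tr$end_f) <= 5))

  # determinism: the same inputs give a byte-identical analysis
  an2 <- analyze_video(vid$frames, seg, cls, fps = 20, k = 4)
  expect_identical(an, an2)
})

test_that("evaluate_system reports both rows with consistent F1", {
  seg <- tiny_seg_model()
  cls <- tiny_cls_model()
  spec <- tiny_spec()
  set.seed(41)
  iphs <- c(rep(0, 8), runif(12, 0.1, 0.5))
  frames <- lapply(seq_along(iphs), function(i)
    render_frame(iphs[i], spec, seed = 820 + i)$image)
  truth <- ifelse(iphs == 0, "disappearance", "existence")
  res <- evaluate_system(frames, truth, seg, cls)
  expect_identical(rownames(res),
                   c("segmentation_only", "segmentation_plus_classifier"))
  for (r in 1:2)
    if (!anyNA(res[r, c("precision", "sensitivity")]))
      expect_equal(res[r, "f1"],
                   f1_score(res[r, "precision"], res[r, "sensitivity"]))
  expect_gte(res["segmentation_plus_classifier", "accuracy"],
             res["segmentation_only", "accuracy"] - 1e-9)
})
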