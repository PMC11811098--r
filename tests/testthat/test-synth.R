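test_that("sample_schedule produces sorted, disjoint, correctly mixed events", {
  expect_identical(sample_schedule(0, 20, 30, 0.5, seed = 7), list())

  sch <- sample_schedule(3, 20, 30, mix = 1.0, seed = 7)
  expect_length(sch, 3)
  expect_true(all(vapply(sch, `[[`, character(1), "label") == "incomplete"))
  # pairwise interval disjointness by brute force
  iv <- t(vapply(sch, function(e)
    c(e$onset_s, e$onset_s + e$closing_s + e$closed_s + e$opening_s),
    numeric(2)))
  for (i in seq_len(nrow(iv)))
    for (j in seq_len(nrow(iv)))
      if (i != j)
        expect_true(iv[i, 2] <= iv[j, 1] || iv[j, 2] <= iv[i, 1])

  # mixed schedules across seeds stay feasible and ordered
  for (s in 1:10) {
    sch <- sample_schedule(6, 20, 30, mix = 0.5, seed = s)
    on <- vapply(sch, `[[`, numeric(1), "onset_s")
    expect_true(all(diff(on) > 0))
    expect_equal(sum(vapply(sch, `[[`, character(1), "label") == "incomplete"), 3)
  }
})

test_that("infeasible packing is rejected and the same seed reproduces", {
  expect_error(sample_schedule(50, 20, 30, 0.5, seed = 7,
                               closing_range = c(0.25, 0.25),
                               opening_range = c(0.25, 0.25)),
               "infeasible")
  expect_identical(sample_schedule(4, 20, 30, 0.5, seed = 11),
                   sample_schedule(4, 20, 30, 0.5, seed = 11))
})

test_that("synthesize_wave builds the piecewise-linear wave with exact truth", {
  # no events: constant at baseline, 600 frames for 20 s at 30 fps
  sp0 <- synth_spec(events = list(), baseline_iph_frac = 0.3)
  sw0 <- synthesize_wave(sp0)
  expect_length(sw0$wave, 600)
  expect_true(all(as.numeric(sw0$wave) == 0.3))
  expect_equal(nrow(sw0$truth$events), 0)

  # one complete event: the minimum is exactly 0 and the zero run matches
  ev <- blink_event_spec(5, closing_s = 0.2, closed_s = 0.2,
                         opening_s = 0.3, trough_frac = 0)
  sp1 <- synth_spec(events = list(ev))
  sw1 <- synthesize_wave(sp1)
  expect_identical(min(as.numeric(sw1$wave)), 0)
  zrun <- rle(as.numeric(sw1$wave) == 0)
  expect_lte(abs(max(zrun$lengths[zrun$values]) - round(0.2 * 30)), 1)

  # closed frame labels coincide exactly with zero noise-free IPH
  expect_identical(sw1$truth$closed, sw1$truth$iph_frac == 0)

  # determinism with noise
  spn <- synth_spec(events = list(ev), wave_noise_sd = 0.01, seed = 42)
  expect_identical(synthesize_wave(spn)$wave, synthesize_wave(spn)$wave)
})

test_that("overlapping or out-of-range events are rejected", {
  e1 <- blink_event_spec(1, 0.2, 0.1, 0.3, 0)
  e2 <- blink_event_spec(1.3, 0.2, 0, 0.3, 0.5)
  expect_error(synth_spec(events = list(e1, e2)), "overlap")
  late <- blink_event_spec(19.9, 0.2, 0.1, 0.3, 0)
  expect_error(synth_spec(events = list(late)), "past the end")
})

test_that("event spec invariants hold", {
  expect_error(blink_event_spec(-1, 0.2, 0, 0.3, 0.5), "onset_s")
  expect_error(blink_event_spec(0, 0, 0, 0.3, 0.5), "positive")
  expect_error(blink_event_spec(0, 0.2, 0.1, 0.3, 0.5), "complete")
  expect_identical(blink_event_spec(0, 0.2, 0, 0.3, 0.4)$label, "incomplete")
  expect_identical(blink_event_spec(0, 0.2, 0.1, 0.3, 0)$label, "complete")
})

test_that("render_frame masks have the requested vertical extent", {
  spec <- synth_spec(image_w = 200, image_h = 600, max_aperture_frac = 0.5)

  expect_identical(sum(render_frame(0, spec)$mask), 0)

  fr <- render_frame(0.20, spec)
  expect_lte(abs(compute_iph(fr$mask)$iph_px - 120), 1)

  fr2 <- render_frame(0.5, spec)
  expect_lte(abs(compute_iph(fr2$mask)$iph_px - 300), 1)

  expect_error(render_frame(0.95, spec), "maximum aperture")
})

test_that("synthesize_video frames/masks are consistent with ground truth", {
  ev <- blink_event_spec(0.8, closing_s = 0.25, closed_s = 0.2,
                         opening_s = 0.3, trough_frac = 0)
  spec <- synth_spec(duration_s = 2.5, fps = 12, image_w = 120, image_h = 90,
                     events = list(ev), pixel_noise_sd = 6, seed = 5)
  vid <- synthesize_video(spec)
  n_empty <- sum(vapply(vid$masks, sum, numeric(1)) == 0)
  expect_identical(n_empty, sum(vid$truth$closed))

  # round trip: wave from the exact masks matches truth within quantization
  w <- wave_from_masks(vid$masks, image_h = spec$image_h, fps = spec$fps)
  expect_true(all(abs(as.numeric(w) - vid$truth$iph_frac) <= 1 / spec$image_h))

  # 0-event spec: all masks identical
  spec0 <- synth_spec(duration_s = 1, fps = 6, image_w = 80, image_h = 60)
  vid0 <- synthesize_video(spec0)
  for (m in vid0$masks) expect_identical(m, vid0$masks[[1]])

  # full determinism
  vid2 <- synthesize_video(spec)
  expect_identical(vid$frames, vid2$frames)
  expect_identical(vid$masks, vid2$masks)
})
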