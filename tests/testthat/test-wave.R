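test_that("run-length rule matches the hand-traced example", {
  w <- blink_wave(c(.10, .10, .10, .08, .06, .04, .02, 0, 0,
                    .02, .04, .06, .08, .10, .10), fps = 30)
  ev <- detect_blink_events(w, k = 5)
  expect_equal(ev$start_f, 3L)   # 4th frame starts the descent's 5-run span
  expect_equal(ev$end_f, 14L)

  # phases of that event: 5 closing steps, 1 closed step, 5 opening steps
  cl <- filter_and_classify_events(ev, w)
  expect_identical(cl$type, "complete")
  expect_equal(cl$closing_s, 5 / 30)
  expect_equal(cl$closed_s, 1 / 30)
  expect_equal(cl$opening_s, 5 / 30)
})

test_that("shallow or short dips do not trigger detection", {
  expect_equal(nrow(detect_blink_events(blink_wave(rep(0.3, 50), 30))), 0)
  # only 3 decreasing steps: no event at k = 5
  w <- blink_wave(c(rep(.1, 5), .08, .06, .04, .06, .08, .1, rep(.1, 5)), 30)
  expect_equal(nrow(detect_blink_events(w, k = 5)), 0)
  expect_equal(nrow(detect_blink_events(w, k = 3)), 1)
})

test_that("classification applies the 80%-of-baseline and zero-trough rules", {
  mk <- function(trough) blink_wave(c(rep(.10, 3), ramp(.10, trough, 6),
                                      ramp(trough, .10, 6), rep(.10, 3)), 30)
  type_of <- function(trough) {
    w <- mk(trough)
    filter_and_classify_events(detect_blink_events(w), w)$type
  }
  expect_identical(type_of(0), "complete")
  expect_identical(type_of(0.04), "incomplete")   # 0.04 <= 0.8 * 0.10
  expect_identical(type_of(0.09), "rejected")     # 0.09 >  0.8 * 0.10
})

test_that("incomplete-blink phases split at the trough frame", {
  # start frame 10 (last baseline frame), trough 16, end 22 (six steps each way)
  w <- blink_wave(c(rep(.2, 10), ramp(.2, .05, 6), ramp(.05, .2, 6),
                    rep(.2, 10)), 30)
  ev <- filter_and_classify_events(detect_blink_events(w), w)
  expect_equal(ev$start_f, 10L)
  expect_equal(ev$trough_f, 16L)
  expect_equal(ev$end_f, 22L)
  expect_equal(ev$closing_s, 0.2)
  expect_equal(ev$closed_s, 0)
  expect_equal(ev$opening_s, 0.2)
  expect_error(phase_durations(list(type = "rejected"), w), "rejected")
})

test_that("detection agrees with an independent brute-force scan", {
  for (s in 1:200) {
    n <- sample(20:300, 1)
    x <- random_wave(n, seed = 1000 + s)
    w <- blink_wave(x, 30)
    k <- sample(2:6, 1)
    got <- detect_blink_events(w, k = k)
    ref <- brute_force_events(x, k)
    expect_identical(got$start_f, ref$start_f,
                     info = sprintf("seed %d k %d", s, k))
    expect_identical(got$end_f, ref$end_f,
                     info = sprintf("seed %d k %d", s, k))
  }
})

test_that("noise-free schedules are recovered exactly", {
  for (s in 1:25) {
    n_ev <- sample(1:6, 1)
    sch <- sample_schedule(n_ev, 20, 30, mix = 0.5, seed = 2000 + s)
    sp <- synth_spec(events = sch, seed = s)
    sw <- synthesize_wave(sp)
    ev <- filter_and_classify_events(detect_blink_events(sw$wave), sw$wave)
    tr <- sw$truth$events
    expect_equal(nrow(ev), nrow(tr))
    expect_identical(ev$type, tr$type)
    expect_true(all(abs(ev$start_f - tr$start_f) <= 1))
    expect_true(all(abs(ev$end_f - tr$end_f) <= 1))
    m <- summarize_metrics(ev, sw$wave)
    expect_identical(m$IB, sum(tr$type == "incomplete"))
    expect_identical(m$CB, sum(tr$type == "complete"))
  }
})

test_that("phases sum to the event duration for every detected event", {
  for (s in 1:10) {
    sch <- sample_schedule(sample(1:5, 1), 20, 30, mix = 0.4, seed = 3000 + s)
    sw <- synthesize_wave(synth_spec(events = sch, seed = s))
    ev <- filter_and_classify_events(detect_blink_events(sw$wave), sw$wave)
    keep <- ev$type != "rejected"
    expect_equal(ev$closing_s[keep] + ev$closed_s[keep] + ev$opening_s[keep],
                 (ev$end_f[keep] - ev$start_f[keep]) / 30)
  }
})

test_that("lowering the rejection threshold never increases blink counts", {
  for (s in 1:20) {
    x <- random_wave(200, seed = 4000 + s)
    w <- blink_wave(x, 30)
    cand <- detect_blink_events(w, k = 3)
    tb <- vapply(c(0.9, 0.8, 0.6, 0.4, 0.2), function(th) {
      ev <- filter_and_classify_events(cand, w, reject_frac = th)
      sum(ev$type != "rejected")
    }, numeric(1))
    expect_true(all(diff(tb) <= 0))
  }
})

test_that("relative IPH% follows its definition", {
  expect_equal(relative_iph(blink_wave(rep(0.25, 10), 30)), 1.0)
  expect_equal(relative_iph(blink_wave(c(0.1, 0.1, 0.0, 0.2), 30)), 0.5)
  expect_error(relative_iph(blink_wave(rep(0, 10), 30)), "all-zero")
  for (s in 1:10) {
    x <- random_wave(100, seed = 5000 + s)
    if (max(x) > 0) {
      r <- relative_iph(blink_wave(x, 30))
      expect_gte(r, 0); expect_lte(r, 1)
    }
  }
})

test_that("summary metrics count events by type", {
  ev <- structure(data.frame(type = c("incomplete", "incomplete", "complete",
                                      "rejected")),
                  class = c("blink_events", "data.frame"))
  m <- summarize_metrics(ev, blink_wave(c(0.1, 0.2), 30))
  expect_identical(c(m$IB, m$CB, m$TB), c(2L, 1L, 3L))
  expect_equal(m$IBR, 2 / 3)

  m0 <- summarize_metrics(ev[ev$type == "rejected", , drop = FALSE],
                          blink_wave(c(0.1, 0.2), 30))
  expect_identical(m0$TB, 0L)
  expect_true(is.na(m0$IBR))

  mc <- summarize_metrics(ev[ev$type == "complete", , drop = FALSE],
                          blink_wave(c(0.1, 0.2), 30))
  expect_identical(mc$IBR, 0)
})

test_that("blink_wave validates its contract", {
  expect_error(blink_wave(c(0.5), 30), "at least 2")
  expect_error(blink_wave(c(0.5, 1.2), 30), "\\[0, 1\\]")
  expect_error(blink_wave(c(0.5, 0.2), 0), "fps")
  expect_error(wave_from_masks(list()), "empty")
})
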