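# Independent brute-force implementation of the run-length blink detection
# rule, used as an oracle against detect_blink_events(). It works directly
# on maximal monotone runs found by explicit scanning, with no shared code
# with the package implementation.
brute_force_events <- function(x, k) {
  n <- length(x)
  step_sign <- function(t) sign(x[t] - x[t + 1])   # +1 while closing
  runs <- list()
  t <- 1L
  while (t <= n - 1L) {
    s <- step_sign(t)
    if (s == 0) { t <- t + 1L; next }
    u <- t
    while (u + 1L <= n - 1L && step_sign(u + 1L) == s) u <- u + 1L
    runs[[length(runs) + 1L]] <- list(s = s, from = t, to = u)
    t <- u + 1L
  }
  out <- data.frame(start_f = integer(0), end_f = integer(0))
  cur <- NA_integer_
  last_end <- 0L
  for (r in runs) {
    if (r$to - r$from + 1L < k) next
    if (r$s > 0 && r$from >= last_end) {
      cur <- r$from                      # keep-latest start
    } else if (r$s < 0 && !is.na(cur)) {
      out <- rbind(out, data.frame(start_f = cur, end_f = r$to + 1L))
      last_end <- r$to + 1L
      cur <- NA_integer_
    }
  }
  out
}

# random test waves: bounded random walks with occasional plateaus, plus
# scheduled synthetic recordings
random_wave <- function(n, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- runif(1, 0, 0.5)
  for (t in 2:n) {
    move <- sample(c(0, 1), 1, prob = c(0.25, 0.75))
    x[t] <- max(0, min(1, x[t - 1] + move * rnorm(1, 0, 0.04)))
  }
  x
}

# frame/mask training set taken from a short synthetic recording, so the
# aperture distribution matches what the pipeline will actually see
# (baseline, ramps, closed)
make_seg_video <- function(n_frames, fps, image_w, image_h, seed,
                           pixel_noise_sd = 5, mix = 0.5,
                           closed_range = c(0.1, 0.2)) {
  sch <- sample_schedule(2, duration_s = n_frames / fps, fps = fps,
                         mix = mix, seed = seed,
                         closed_range = closed_range)
  spec <- synth_spec(duration_s = n_frames / fps, fps = fps,
                     image_w = image_w, image_h = image_h,
                     baseline_iph_frac = 0.35, events = sch,
                     pixel_noise_sd = pixel_noise_sd, seed = seed)
  synthesize_video(spec)
}

# linear ramp with exact endpoints (avoids 1-ulp excursions below zero)
ramp <- function(from, to, n) {
  v <- from + (to - from) * (seq_len(n) / n)
  v[n] <- to
  v
}
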