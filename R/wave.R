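#' Construct a blink wave
#'
#' A blink wave is the per-frame interpalpebral height expressed as a
#' fraction of image height (IPH\%), together with the frame rate. It is the
#' central time-series object of the package: one trough per blink.
#'
#' @param iph_frac Numeric vector of per-frame IPH fractions, each in
#'   `[0, 1]`, length >= 2.
#' @param fps Frame rate in frames per second (> 0).
#' @return An object of class `"blink_wave"`: a numeric vector with
#'   attribute `fps`. `time_s(wave)` gives the time axis
#'   `(frame - 1) / fps`; frame indices are 1-based throughout.
#' @examples
#' w <- blink_wave(c(0.3, 0.3, 0.2, 0.1, 0.2, 0.3), fps = 30)
#' time_s(w)
#' @export
blink_wave <- function(iph_frac, fps) {
  iph_frac <- as.numeric(iph_frac)
  if (length(iph_frac) < 2) stopf("a blink wave needs at least 2 frames")
  if (anyNA(iph_frac)) stopf("blink wave contains NA")
  if (any(iph_frac < 0 | iph_frac > 1))
    stopf("IPH fractions must lie in [0, 1]")
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stopf("fps must be a single positive number")
  structure(iph_frac, fps = fps, class = "blink_wave")
}

#' @rdname blink_wave
#' @param wave A `blink_wave`.
#' @export
time_s <- function(wave) (seq_along(wave) - 1) / attr(wave, "fps")

#' @export
print.blink_wave <- function(x, ...) {
  fps <- attr(x, "fps")
  cat(sprintf("Blink wave: %d frames @ %g fps (%.2f s), IPH%% range %.1f-%.1f%%\n",
              length(x), fps, length(x) / fps,
              100 * min(x), 100 * max(x)))
  invisible(x)
}

#' Build a blink wave from per-frame masks and open/closed labels
#'
#' Computes each frame's IPH from its segmentation mask, applies the
#' open/closed correction (a frame labelled "disappearance" is forced to
#' zero height), and normalizes by the image height.
#'
#' @param masks List of binary masks (one per frame).
#' @param labels Optional character vector of per-frame states,
#'   `"existence"` or `"disappearance"`; when `NULL` no correction is
#'   applied.
#' @param image_h Image height in pixels used for normalization.
#' @param fps Frame rate (frames/s).
#' @return A [blink_wave()].
#' @export
wave_from_masks <- function(masks, labels = NULL, image_h = NULL, fps = 30) {
  if (length(masks) == 0) stopf("empty mask sequence")
  if (is.null(image_h)) image_h <- nrow(masks[[1]])
  if (!is.null(labels) && length(labels) != length(masks))
    stopf("labels and masks must be aligned")
  iph <- vapply(masks, function(m) compute_iph(m, image_h)$iph_px, numeric(1))
  if (!is.null(labels)) iph <- correct_iph(labels, iph)
  blink_wave(pmin(iph / image_h, 1), fps)
}

#' Detect candidate blink events with the run-length rule
#'
#' Scans the frame-to-frame IPH\% differences
#' `delta[t] = iph[t] - iph[t + 1]` (positive while the eye is closing). A
#' blink start is the first frame of a run of at least `k` strictly positive
#' differences; the matching end is the last frame of the next run of at
#' least `k` strictly negative differences (where the reopening of the eye
#' stops). A start superseded by a later start before any end is discarded
#' (keep-latest),
#' and a start with no matching end before the recording ends is dropped, so
#' the returned intervals are ordered and non-overlapping.
#'
#' @param wave A [blink_wave()].
#' @param k Run length (number of consecutive differences), default 5: at 30
#'   frames/s this requires closing/opening ramps of at least 0.2 s, so
#'   consider lowering `k` for recordings with very fast blinks.
#' @param median_filter If `TRUE`, apply a 3-frame running median before
#'   differencing (off by default; useful for noisy waves). Detection
#'   indices still refer to the original wave.
#' @return Data frame with 1-based integer columns `start_f`, `end_f`.
#' @examples
#' w <- blink_wave(c(.10, .10, .10, .08, .06, .04, .02, 0, 0,
#'                   .02, .04, .06, .08, .10, .10), fps = 30)
#' detect_blink_events(w) # one event: frames 3..14
#' @export
detect_blink_events <- function(wave, k = 5L, median_filter = FALSE) {
  stopifnot(inherits(wave, "blink_wave"))
  k <- as.integer(k)
  if (k < 1) stopf("k must be >= 1")
  x <- as.numeric(wave)
  if (median_filter) x <- running_median3(x)
  n <- length(x)
  m <- n - 1L                       # number of differences
  empty <- data.frame(start_f = integer(0), end_f = integer(0))
  if (m < k) return(empty)
  d <- x[-n] - x[-1]                # d[t] = iph[t] - iph[t+1]
  pos <- d > 0
  neg <- d < 0
  # running length of the TRUE-run ending at t
  runlen <- function(b) {
    r <- integer(length(b))
    acc <- 0L
    for (t in seq_along(b)) {
      acc <- if (b[t]) acc + 1L else 0L
      r[t] <- acc
    }
    r
  }
  rp <- runlen(pos)
  rn <- runlen(neg)
  starts <- integer(0)
  ends <- integer(0)
  cur <- NA_integer_
  t <- k
  while (t <= m) {
    if (!is.na(cur) && rn[t] == k) {
      t2 <- t                       # extend to the end of the negative run
      while (t2 < m && neg[t2 + 1L]) t2 <- t2 + 1L
      starts <- c(starts, cur)
      ends <- c(ends, t2 + 1L)      # last frame of the run
      cur <- NA_integer_
      t <- t2 + 1L                  # resume at the end frame
      next
    }
    if (rp[t] == k) cur <- t - k + 1L   # first frame of the run; keep-latest
    t <- t + 1L
  }
  if (length(starts) == 0) return(empty)
  data.frame(start_f = as.integer(starts), end_f = as.integer(ends))
}

running_median3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- vapply(2:(n - 1),
                         function(i) median(x[(i - 1):(i + 1)]), numeric(1))
  y
}

#' Classify candidate events and attach phase durations
#'
#' Applies the baseline filter and the completeness rule to the candidate
#' intervals from [detect_blink_events()]: with baseline the IPH\% at the
#' start frame and trough the minimum IPH\% over the interval, an event
#' whose trough exceeds 80\% of its baseline is rejected (too shallow to be
#' a blink); a trough of exactly 0\% marks a complete blink; anything else
#' is incomplete. Closing/closed/opening phase durations are attached via
#' [phase_durations()] (rejected events get `NA` durations).
#'
#' @param candidates Data frame from [detect_blink_events()].
#' @param wave The [blink_wave()] the candidates were detected on.
#' @param reject_frac Rejection threshold as a fraction of baseline
#'   (default 0.8).
#' @return A data frame of class `"blink_events"` with columns `start_f`,
#'   `trough_f`, `end_f`, `baseline_frac`, `trough_frac`, `type`
#'   (`"complete"`, `"incomplete"` or `"rejected"`), `closing_s`,
#'   `closed_s`, `opening_s`.
#' @export
filter_and_classify_events <- function(candidates, wave, reject_frac = 0.8) {
  stopifnot(inherits(wave, "blink_wave"))
  x <- as.numeric(wave)
  fps <- attr(wave, "fps")
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    s <- candidates$start_f[i]; e <- candidates$end_f[i]
    seg <- x[s:e]
    trough <- min(seg)
    trough_f <- s + which.min(seg) - 1L   # first frame attaining the trough
    baseline <- x[s]
    type <- if (trough > reject_frac * baseline) "rejected"
            else if (trough == 0) "complete" else "incomplete"
    ev <- data.frame(start_f = s, trough_f = trough_f, end_f = e,
                     baseline_frac = baseline, trough_frac = trough,
                     type = type, stringsAsFactors = FALSE)
    ph <- if (type == "rejected") list(closing_s = NA_real_,
                                       closed_s = NA_real_,
                                       opening_s = NA_real_)
          else phase_durations(ev, wave)
    ev$closing_s <- ph$closing_s; ev$closed_s <- ph$closed_s
    ev$opening_s <- ph$opening_s
    ev
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_f = integer(0), trough_f = integer(0),
               end_f = integer(0), baseline_frac = numeric(0),
               trough_frac = numeric(0), type = character(0),
               closing_s = numeric(0), closed_s = numeric(0),
               opening_s = numeric(0), stringsAsFactors = FALSE)
  class(res) <- c("blink_events", "data.frame")
  attr(res, "fps") <- fps
  res
}

#' Phase durations of one blink event
#'
#' Splits a detected blink into its three phases. For a complete blink the
#' closed phase is the zero-run containing the trough: with `t_c1`/`t_c2`
#' its first/last frame, closing is `(t_c1 - start_f) / fps`, closed is
#' `(t_c2 - t_c1) / fps` and opening is `(end_f - t_c2) / fps`. For an
#' incomplete blink there is no closed phase: closing ends at the first
#' frame attaining the trough and opening covers the rest. The three
#' durations always sum to `(end_f - start_f) / fps`.
#'
#' @param event One-row data frame (or list) with `start_f`, `trough_f`,
#'   `end_f`, `type`; must not be a rejected event.
#' @param wave The [blink_wave()] the event belongs to.
#' @return List with `closing_s`, `closed_s`, `opening_s` (seconds).
#' @export
phase_durations <- function(event, wave) {
  stopifnot(inherits(wave, "blink_wave"))
  if (event$type == "rejected")
    stopf("phase durations are undefined for rejected events")
  x <- as.numeric(wave)
  fps <- attr(wave, "fps")
  s <- event$start_f; e <- event$end_f; tf <- event$trough_f
  if (event$type == "complete") {
    zero <- which(x[s:e] == 0) + s - 1L
    # zero-run containing the trough frame
    runs <- split(zero, cumsum(c(1L, diff(zero) != 1L)))
    run <- runs[[which(vapply(runs, function(r) tf %in% r, logical(1)))[1]]]
    t_c1 <- min(run); t_c2 <- max(run)
    list(closing_s = (t_c1 - s) / fps, closed_s = (t_c2 - t_c1) / fps,
         opening_s = (e - t_c2) / fps)
  } else {
    list(closing_s = (tf - s) / fps, closed_s = 0,
         opening_s = (e - tf) / fps)
  }
}

#' Relative IPH\% of a recording
#'
#' The ratio of the mean IPH\% over the recording to its maximum IPH\%. A
#' value near 1 means the eye stayed near its widest aperture (few or
#' shallow blinks); lower values indicate a greater extent of (incomplete)
#' blinking activity relative to the widest opening.
#'
#' @param wave A [blink_wave()].
#' @return A fraction in `[0, 1]`.
#' @examples
#' relative_iph(blink_wave(c(0.1, 0.1, 0.0, 0.2), fps = 30)) # 0.5
#' @export
relative_iph <- function(wave) {
  stopifnot(inherits(wave, "blink_wave"))
  mx <- max(wave)
  if (mx == 0) stopf("relative IPH%% is undefined for an all-zero wave")
  mean(wave) / mx
}

#' Summarize blink metrics for one recording
#'
#' Counts complete (CB) and incomplete (IB) blinks among non-rejected
#' events, the total (TB = IB + CB), the incomplete blinking rate
#' (IBR = IB / TB, `NA` when TB = 0), and attaches the recording's relative
#' IPH\%.
#'
#' @param events A `"blink_events"` data frame from
#'   [filter_and_classify_events()].
#' @param wave The corresponding [blink_wave()].
#' @return A list of class `"blink_metrics"` with elements `IB`, `CB`, `TB`,
#'   `IBR`, `relative_iph`.
#' @export
summarize_metrics <- function(events, wave) {
  ib <- sum(events$type == "incomplete")
  cb <- sum(events$type == "complete")
  tb <- ib + cb
  structure(list(IB = ib, CB = cb, TB = tb,
                 IBR = if (tb > 0) ib / tb else NA_real_,
                 relative_iph = relative_iph(wave)),
            class = "blink_metrics")
}

#' @export
print.blink_metrics <- function(x, ...) {
  cat(sprintf("Blinks: %d total (%d complete, %d incomplete)\n",
              x$TB, x$CB, x$IB))
  cat(sprintf("  incomplete blinking rate: %s\n",
              if (is.na(x$IBR)) "undefined (no blinks)"
              else sprintf("%.4f", x$IBR)))
  cat(sprintf("  relative IPH%%: %.4f\n", x$relative_iph))
  invisible(x)
}

#' Plot a blink wave with event markers
#'
#' Draws IPH\% against time with, for each non-rejected event, the start of
#' the closing phase (purple), the trough (red) and the end of the opening
#' phase (black) marked.
#'
#' @param x A [blink_wave()].
#' @param events Optional `"blink_events"` data frame to annotate.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.blink_wave <- function(x, events = NULL, ...) {
  tt <- time_s(x)
  graphics::plot(tt, 100 * as.numeric(x), type = "l",
                 xlab = "time (s)", ylab = "IPH%", ...)
  if (!is.null(events) && nrow(events)) {
    keep <- events$type != "rejected"
    ev <- events[keep, , drop = FALSE]
    graphics::points(tt[ev$start_f], 100 * x[ev$start_f], col = "purple",
                     pch = 19)
    graphics::points(tt[ev$trough_f], 100 * x[ev$trough_f], col = "red",
                     pch = 19)
    graphics::points(tt[ev$end_f], 100 * x[ev$end_f], col = "black",
                     pch = 19)
  }
  invisible(x)
}
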