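#' Specify one synthetic blink event
#'
#' A blink event is a descend/hold/ascend excursion of the interpalpebral
#' height: the lids close over `closing_s` seconds, stay at the trough for
#' `closed_s` seconds (zero for incomplete blinks, which never reach full
#' closure), and reopen over `opening_s` seconds.
#'
#' @param onset_s Event onset (start of the closing phase), seconds from the
#'   beginning of the recording.
#' @param closing_s,opening_s Durations of the closing and opening ramps in
#'   seconds; both must be positive.
#' @param closed_s Duration of the fully-closed plateau in seconds; must be 0
#'   for incomplete blinks and may be 0 or positive for complete ones.
#' @param trough_frac Trough depth as a fraction of the pre-blink baseline in
#'   `[0, 1]`; exactly 0 denotes a complete blink.
#' @return An object of class `"blink_event_spec"`.
#' @examples
#' blink_event_spec(2, closing_s = 0.2, closed_s = 0.1, opening_s = 0.3,
#'                  trough_frac = 0)
#' @export
blink_event_spec <- function(onset_s, closing_s, closed_s, opening_s,
                             trough_frac) {
  if (onset_s < 0) stopf("onset_s must be >= 0")
  if (closing_s <= 0 || opening_s <= 0)
    stopf("closing_s and opening_s must be positive")
  if (closed_s < 0) stopf("closed_s must be >= 0")
  if (trough_frac < 0 || trough_frac > 1)
    stopf("trough_frac must be in [0, 1]")
  label <- if (trough_frac == 0) "complete" else "incomplete"
  if (label == "incomplete" && closed_s > 0)
    stopf("closed_s > 0 requires a complete blink (trough_frac = 0)")
  structure(list(onset_s = onset_s, closing_s = closing_s,
                 closed_s = closed_s, opening_s = opening_s,
                 trough_frac = trough_frac, label = label),
            class = "blink_event_spec")
}

event_duration <- function(ev) ev$closing_s + ev$closed_s + ev$opening_s

#' Specify a synthetic eye recording
#'
#' Collects the generative parameters for a synthetic single-eye recording:
#' a constant open-eye baseline interrupted by a schedule of blink events,
#' with optional Gaussian noise on the waveform and on rendered pixels. The
#' defaults mirror a standard interferometer acquisition: 20 s at 30
#' frames/s, 800 x 600 pixels.
#'
#' @param duration_s Recording length in seconds.
#' @param fps Frame rate, frames per second.
#' @param baseline_iph_frac Open-eye interpalpebral height as a fraction of
#'   the image height; must not exceed `max_aperture_frac`.
#' @param events List of [blink_event_spec()] objects; must be pairwise
#'   non-overlapping (separated by at least one frame) and lie inside
#'   `[0, duration_s]`.
#' @param wave_noise_sd Standard deviation of additive Gaussian noise on the
#'   IPH\% waveform (fraction-of-height units); the noisy wave is clipped to
#'   `[0, 1]`.
#' @param pixel_noise_sd Standard deviation of additive Gaussian pixel noise
#'   in 8-bit gray levels; applied to rendered frames only, never to masks.
#' @param image_w,image_h Frame size in pixels.
#' @param max_aperture_frac Geometric maximum aperture the eye model can
#'   draw, as a fraction of image height.
#' @param seed Integer seed driving all randomness derived from this spec.
#' @return An object of class `"synth_spec"`.
#' @seealso [synthesize_wave()], [synthesize_video()], [sample_schedule()]
#' @export
synth_spec <- function(duration_s = 20, fps = 30, baseline_iph_frac = 0.35,
                       events = list(), wave_noise_sd = 0,
                       pixel_noise_sd = 0, image_w = 800, image_h = 600,
                       max_aperture_frac = 0.5, seed = 1L) {
  if (duration_s <= 0 || fps <= 0) stopf("duration_s and fps must be positive")
  if (baseline_iph_frac <= 0 || baseline_iph_frac > max_aperture_frac)
    stopf("baseline_iph_frac must be in (0, max_aperture_frac]")
  if (wave_noise_sd < 0 || pixel_noise_sd < 0) stopf("noise sd must be >= 0")
  if (image_w < 8 || image_h < 8) stopf("image too small")
  events <- lapply(events, function(e) {
    if (!inherits(e, "blink_event_spec")) stopf("events must be blink_event_spec")
    e
  })
  if (length(events)) {
    ord <- order(vapply(events, `[[`, numeric(1), "onset_s"))
    events <- events[ord]
    ends <- vapply(events, function(e) e$onset_s + event_duration(e),
                   numeric(1))
    starts <- vapply(events, `[[`, numeric(1), "onset_s")
    if (any(ends > duration_s))
      stopf("event extends past the end of the recording")
    if (length(events) > 1 &&
        any(starts[-1] - ends[-length(ends)] < 1 / fps))
      stopf("events overlap or are separated by less than one frame")
  }
  structure(list(duration_s = duration_s, fps = fps,
                 baseline_iph_frac = baseline_iph_frac, events = events,
                 wave_noise_sd = wave_noise_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 image_w = as.integer(image_w), image_h = as.integer(image_h),
                 max_aperture_frac = max_aperture_frac,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("Synthetic eye recording: %.3g s @ %g fps, %d x %d px\n",
              x$duration_s, x$fps, x$image_w, x$image_h))
  cat(sprintf("  baseline IPH%%: %.1f%%  events: %d (%d complete, %d incomplete)\n",
              100 * x$baseline_iph_frac, length(x$events),
              sum(vapply(x$events, `[[`, character(1), "label") == "complete"),
              sum(vapply(x$events, `[[`, character(1), "label") == "incomplete")))
  cat(sprintf("  noise: wave sd %.3g, pixel sd %.3g gray levels; seed %d\n",
              x$wave_noise_sd, x$pixel_noise_sd, x$seed))
  invisible(x)
}

#' Sample a random, feasible blink schedule
#'
#' Draws `n_events` non-overlapping blink events uniformly at random inside
#' the recording, separated by at least one frame of baseline so that
#' adjacent events can never merge under the run-length detection rule.
#' Complete/incomplete labels are assigned so that `round(mix * n_events)`
#' events are incomplete. Durations are drawn from ranges typical of human
#' blinks while keeping both ramps at least `min_ramp_s` long.
#'
#' @param n_events Number of events (>= 0).
#' @param duration_s,fps Recording length (s) and frame rate (frames/s).
#' @param mix Target fraction of incomplete blinks in `[0, 1]`.
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @param closing_range,opening_range,closed_range Duration ranges (s) for
#'   the three phases; closed-phase durations apply to complete blinks only.
#' @param trough_range Range of incomplete-blink trough depths as a fraction
#'   of baseline; keep the upper end below 0.8 so sampled events are never
#'   rejected by the 80\%-of-baseline rule.
#' @param min_ramp_s Minimum ramp duration (s).
#' @return A list of [blink_event_spec()] objects sorted by onset.
#' @examples
#' sched <- sample_schedule(4, duration_s = 20, fps = 30, mix = 0.5, seed = 7)
#' vapply(sched, `[[`, character(1), "label")
#' @export
sample_schedule <- function(n_events, duration_s = 20, fps = 30, mix = 0.5,
                            seed = 1L,
                            closing_range = c(0.2, 0.35),
                            opening_range = c(0.25, 0.45),
                            closed_range = c(0.05, 0.15),
                            trough_range = c(0.15, 0.7),
                            min_ramp_s = 0.2) {
  if (n_events < 0) stopf("n_events must be >= 0")
  if (n_events == 0) return(list())
  if (mix < 0 || mix > 1) stopf("mix must be in [0, 1]")
  closing_range <- pmax(closing_range, min_ramp_s)
  opening_range <- pmax(opening_range, min_ramp_s)
  with_seed(seed, {
    n_inc <- round(mix * n_events)
    labels <- sample(c(rep("incomplete", n_inc),
                       rep("complete", n_events - n_inc)))
    closing <- runif(n_events, closing_range[1], closing_range[2])
    opening <- runif(n_events, opening_range[1], opening_range[2])
    closed <- ifelse(labels == "complete",
                     runif(n_events, closed_range[1], closed_range[2]), 0)
    trough <- ifelse(labels == "incomplete",
                     runif(n_events, trough_range[1], trough_range[2]), 0)
    dur <- closing + closed + opening
    gap <- 1.5 / fps                      # guaranteed baseline separation
    free <- duration_s - sum(dur) - (n_events + 1) * gap
    if (free < 0)
      stopf("infeasible schedule: %d events need %.2f s but only %.2f s available",
            n_events, sum(dur) + (n_events + 1) * gap, duration_s)
    w <- runif(n_events + 1)
    slack <- free * w / sum(w)
    onsets <- numeric(n_events)
    t0 <- 0
    for (i in seq_len(n_events)) {
      t0 <- t0 + gap + slack[i]
      onsets[i] <- t0
      t0 <- t0 + dur[i]
    }
    lapply(seq_len(n_events), function(i)
      blink_event_spec(onsets[i], closing[i], closed[i], opening[i],
                       trough[i]))
  })
}

#' Synthesize a blink wave with exact ground truth
#'
#' Builds the noise-free IPH\% time series implied by a [synth_spec()]:
#' constant at the open-eye baseline outside events; inside an event the wave
#' descends linearly to the trough over the closing phase, holds through the
#' closed phase, and ascends linearly back over the opening phase. Gaussian
#' noise of sd `wave_noise_sd` is then added and the result clipped to
#' `[0, 1]`.
#'
#' @param spec A [synth_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{wave}{a [blink_wave()] of the (possibly noisy) series,}
#'     \item{truth}{ground truth: `iph_frac` (noise-free series),
#'       `closed` (logical per-frame closed labels, true exactly where the
#'       noise-free wave is 0), and `events`, a data frame of per-event
#'       `start_f`, `trough_f`, `end_f` (1-based frame indices) and `type`.}
#'   }
#' @examples
#' spec <- synth_spec(duration_s = 4, events = sample_schedule(2, 4, seed = 3))
#' sw <- synthesize_wave(spec)
#' sw$truth$events
#' @export
synthesize_wave <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$duration_s * spec$fps)
  fps <- spec$fps
  b <- spec$baseline_iph_frac
  clean <- rep(b, n)
  ev_rows <- lapply(spec$events, function(e) {
    o <- round(e$onset_s * fps) + 1L           # 1-based onset frame
    nc <- max(1L, round(e$closing_s * fps))
    nh <- round(e$closed_s * fps)
    no <- max(1L, round(e$opening_s * fps))
    trough <- e$trough_frac * b
    if (o + nc + nh + no > n) stopf("event extends past the last frame")
    clean[o + seq_len(nc)] <<- b - (b - trough) * (seq_len(nc) / nc)
    clean[o + nc] <<- trough           # ramp endpoints exact
    if (nh > 0) clean[o + nc + seq_len(nh)] <<- trough
    clean[o + nc + nh + seq_len(no)] <<-
      trough + (b - trough) * (seq_len(no) / no)
    clean[o + nc + nh + no] <<- b
    data.frame(start_f = o, trough_f = o + nc, end_f = o + nc + nh + no,
               type = e$label, stringsAsFactors = FALSE)
  })
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(start_f = integer(0), trough_f = integer(0),
               end_f = integer(0), type = character(0),
               stringsAsFactors = FALSE)
  iph <- clean
  if (spec$wave_noise_sd > 0) {
    iph <- with_seed(spec$seed, iph + rnorm(n, 0, spec$wave_noise_sd))
    iph <- pmin(pmax(iph, 0), 1)
  }
  list(wave = blink_wave(iph, fps),
       truth = list(iph_frac = clean, closed = clean == 0, events = events,
                    baseline = b))
}
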