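# End-to-end orchestration: dataset generation on disk, full-video
# analysis (frames -> masks -> open/closed labels -> corrected wave ->
# events -> metrics), and the two-row system evaluation comparing the
# segmenter alone against segmenter + classifier correction.

#' Largest-remainder split of n items into train/validation/test
#'
#' Indices are shuffled with the supplied seed, then sizes are assigned by
#' largest-remainder rounding of the requested proportions (ties go to the
#' earlier set), so every set is non-empty whenever `n` is at least 10 with
#' the default 8:1:1 proportions.
#'
#' @param n Number of items.
#' @param split Proportions for train, validation, test (summing to 1).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @examples
#' lengths(split_indices(1440, seed = 1)) # 1152, 144, 144
#' @export
split_indices <- function(n, split = c(8, 1, 1) / 10, seed = NULL) {
  if (abs(sum(split) - 1) > 1e-8) stopf("split proportions must sum to 1")
  sizes <- floor(n * split)
  rem <- n * split - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1L
  }
  perm <- if (is.null(seed)) sample.int(n) else
    with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1])]),
       val = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Generate a synthetic dataset on disk
#'
#' Streams a full synthetic recording to `out_dir`: grayscale frames under
#' `frames/`, exact masks under `masks/` (0/255 PNGs), the noisy wave as
#' `wave.csv`, the noise-free ground truth as `ground_truth.csv` (frame,
#' time_s, iph_pct, closed_label) and `schedule.json` (per-event indices and
#' types), the spec itself as `spec.yaml`, and a `manifest.csv` with columns
#' `frame_path`, `mask_path`, `state`, `split` using a seeded 8:1:1
#' largest-remainder split.
#'
#' @param spec A [synth_spec()] or the path to its YAML representation.
#' @param out_dir Output directory (created if needed).
#' @param split Train/validation/test proportions.
#' @return The manifest data frame, invisibly; `attr(, "dir")` holds
#'   `out_dir`.
#' @export
generate_dataset <- function(spec, out_dir, split = c(8, 1, 1) / 10) {
  if (is.character(spec)) spec <- read_synth_spec(spec)
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(file.path(out_dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  sw <- synthesize_wave(spec)
  n <- length(sw$truth$iph_frac)
  seeds <- derive_seeds(spec$seed, n + 1L)
  frame_paths <- file.path("frames", sprintf("frame_%05d.png", seq_len(n)))
  mask_paths <- file.path("masks", sprintf("mask_%05d.png", seq_len(n)))
  for (i in seq_len(n)) {
    fr <- render_frame(sw$truth$iph_frac[i], spec, seed = seeds[i])
    write_frame_png(fr$image, file.path(out_dir, frame_paths[i]))
    write_mask_png(fr$mask, file.path(out_dir, mask_paths[i]))
  }
  write_wave_csv(sw$wave, file.path(out_dir, "wave.csv"))
  gt <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / spec$fps,
                   iph_pct = 100 * sw$truth$iph_frac,
                   closed_label = as.integer(sw$truth$closed))
  write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(sw$truth$events,
                       file.path(out_dir, "schedule.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  write_synth_spec(spec, file.path(out_dir, "spec.yaml"))
  sp <- split_indices(n, split, seed = seeds[n + 1L])
  split_lab <- character(n)
  split_lab[sp$train] <- "train"; split_lab[sp$val] <- "val"
  split_lab[sp$test] <- "test"
  manifest <- data.frame(frame_path = frame_paths, mask_path = mask_paths,
                         state = ifelse(sw$truth$closed, "disappearance",
                                        "existence"),
                         split = split_lab, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

# lightweight provenance checksum of a numeric parameter collection
param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  sprintf("%.10e:%d", sum(v * seq_along(v) %% 977), length(v))
}

#' Analyze a recording end to end
#'
#' Runs the full pipeline on a recording: each frame is segmented, the
#' open/closed classifier verifies it (closed calls force the IPH to zero),
#' the corrected IPH\% series forms the blink wave, and the run-length rule,
#' baseline filter and phase decomposition produce events and summary
#' metrics. The result is deterministic given fixed models and
#' configuration.
#'
#' @param video A directory of frame PNGs (analyzed in file-name order), a
#'   list of grayscale matrices, or an h x w x n array.
#' @param seg_model A `"blink_unet"` from [train_segmentation()].
#' @param cls_model Optional `"blink_swin"` from [train_classifier()]; when
#'   `NULL` no open/closed correction is applied.
#' @param fps Frame rate in frames/s; required (frame directories carry no
#'   timing metadata).
#' @param k,reject_frac Detection run length and baseline rejection
#'   threshold (see [detect_blink_events()] and
#'   [filter_and_classify_events()]).
#' @param max_duration_s Recordings longer than this are trimmed to their
#'   first `max_duration_s` seconds (default 20, the standard analysis
#'   window); `Inf` disables trimming.
#' @return An object of class `"blink_analysis"`: `wave`, `events`,
#'   `metrics`, and `provenance` (frame count, fps, thresholds, model
#'   checksums).
#' @export
analyze_video <- function(video, seg_model, cls_model = NULL, fps = NULL,
                          k = 5L, reject_frac = 0.8, max_duration_s = 20) {
  if (is.null(fps)) stopf("fps is required (not stored in frame directories)")
  frames <- load_frames(video)
  if (length(frames) == 0) stopf("no frames found")
  nmax <- floor(max_duration_s * fps)
  if (length(frames) > nmax) frames <- frames[seq_len(nmax)]
  image_h <- nrow(frames[[1]])
  masks <- lapply(frames, segment_frame, model = seg_model)
  labels <- if (!is.null(cls_model))
    vapply(frames, function(f) classify_frame(cls_model, f)$state,
           character(1)) else NULL
  wave <- wave_from_masks(masks, labels, image_h = image_h, fps = fps)
  events <- filter_and_classify_events(detect_blink_events(wave, k = k),
                                       wave, reject_frac = reject_frac)
  metrics <- summarize_metrics(events, wave)
  structure(list(wave = wave, events = events, metrics = metrics,
                 provenance = list(
                   n_frames = length(frames), fps = fps, k = as.integer(k),
                   reject_frac = reject_frac,
                   seg_checksum = param_checksum(seg_model$weights),
                   cls_checksum = if (is.null(cls_model)) NA_character_
                                  else param_checksum(cls_model$params))),
            class = "blink_analysis")
}

load_frames <- function(video) {
  if (is.character(video)) {
    if (!dir.exists(video))
      stopf("'%s' is not a readable frame directory", video)
    paths <- sort(list.files(video, pattern = "\\.png$", full.names = TRUE))
    lapply(paths, read_frame_png)
  } else if (is.list(video)) {
    video
  } else if (is.array(video) && length(dim(video)) == 3) {
    lapply(seq_len(dim(video)[3]), function(i) video[, , i])
  } else stopf("video must be a frame directory, list of matrices, or array")
}

#' Analyze a blink wave directly
#'
#' Wave-only entry point for recordings whose IPH\% series already exists
#' (e.g. exported as CSV): detection, classification and summary without the
#' imaging stages.
#'
#' @param wave A [blink_wave()] or path to a wave CSV (see
#'   [read_wave_csv()]).
#' @inheritParams analyze_video
#' @return A `"blink_analysis"` (with segmentation provenance absent).
#' @export
analyze_wave <- function(wave, fps = NULL, k = 5L, reject_frac = 0.8) {
  if (is.character(wave)) wave <- read_wave_csv(wave, fps = fps)
  stopifnot(inherits(wave, "blink_wave"))
  events <- filter_and_classify_events(detect_blink_events(wave, k = k),
                                       wave, reject_frac = reject_frac)
  structure(list(wave = wave, events = events,
                 metrics = summarize_metrics(events, wave),
                 provenance = list(n_frames = length(wave),
                                   fps = attr(wave, "fps"),
                                   k = as.integer(k),
                                   reject_frac = reject_frac,
                                   seg_checksum = NA_character_,
                                   cls_checksum = NA_character_)),
            class = "blink_analysis")
}

#' @export
print.blink_analysis <- function(x, ...) {
  print(x$wave)
  print(x$metrics)
  invisible(x)
}

#' @export
summary.blink_analysis <- function(object, ...) {
  print(object)
  ev <- object$events[object$events$type != "rejected", , drop = FALSE]
  if (nrow(ev)) {
    cat("Events:\n")
    print.data.frame(ev, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
plot.blink_analysis <- function(x, ...) {
  plot(x$wave, events = x$events, ...)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (events, metrics, provenance), `events.csv`,
#' `wave.csv`, and a Fig-2-style annotated wave plot `wave.png`.
#'
#' @param analysis A `"blink_analysis"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis_report <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "blink_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(events = as.data.frame(analysis$events),
         metrics = analysis$metrics[!vapply(analysis$metrics, is.na,
                                            logical(1))],
         provenance = analysis$provenance),
    file.path(out_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(as.data.frame(analysis$events),
            file.path(out_dir, "events.csv"), row.names = FALSE)
  write_wave_csv(analysis$wave, file.path(out_dir, "wave.csv"))
  grDevices::png(file.path(out_dir, "wave.png"), width = 900, height = 360)
  plot(analysis)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Compare per-frame state calls of the segmenter alone vs. with correction
#'
#' The segmenter-alone system calls a frame "disappearance" exactly when its
#' (uncorrected) IPH is zero; the combined system applies the classifier's
#' correction first, so a frame is "disappearance" when the classifier says
#' so or the corrected IPH is zero. Both rows use the same metric
#' definitions with disappearance as the positive class.
#'
#' @param iph_px Per-frame IPH in pixels from segmentation (uncorrected).
#' @param cls_states Per-frame classifier states
#'   (`"existence"`/`"disappearance"`).
#' @param truth_states Ground-truth per-frame states.
#' @return Data frame with rows `segmentation_only` and
#'   `segmentation_plus_classifier` and columns accuracy, f1, precision,
#'   sensitivity, specificity.
#' @export
compare_frame_systems <- function(iph_px, cls_states, truth_states) {
  if (length(iph_px) != length(truth_states) ||
      length(cls_states) != length(truth_states))
    stopf("inputs must be aligned")
  seg_only <- ifelse(iph_px == 0, "disappearance", "existence")
  corrected <- correct_iph(cls_states, iph_px)
  combined <- ifelse(corrected == 0, "disappearance", "existence")
  row <- function(pred) {
    m <- evaluate_frame_classification(pred, truth_states)
    data.frame(accuracy = m$accuracy, f1 = m$f1, precision = m$precision,
               sensitivity = m$sensitivity, specificity = m$specificity)
  }
  out <- rbind(segmentation_only = row(seg_only),
               segmentation_plus_classifier = row(combined))
  out
}

#' Evaluate the two-model system on labeled frames
#'
#' Runs segmentation (and classification) on each frame and reports the
#' frame-state metrics of the segmenter alone and of the combined system
#' (see [compare_frame_systems()]).
#'
#' @param frames List of grayscale matrices.
#' @param truth_states Ground-truth states, `"existence"` or
#'   `"disappearance"`.
#' @param seg_model A `"blink_unet"`.
#' @param cls_model A `"blink_swin"`.
#' @return The two-row data frame of [compare_frame_systems()].
#' @export
evaluate_system <- function(frames, truth_states, seg_model, cls_model) {
  if (length(frames) == 0) stopf("no frames supplied")
  if (length(truth_states) != length(frames))
    stopf("missing ground-truth labels")
  iph <- vapply(frames, function(f)
    compute_iph(segment_frame(seg_model, f))$iph_px, numeric(1))
  states <- vapply(frames, function(f) classify_frame(cls_model, f)$state,
                   character(1))
  compare_frame_systems(iph, states, truth_states)
}
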