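# Plain-file interfaces: PNG frames and masks, CSV waves, YAML specs,
# JSON reports.

#' Read and write blink waves as CSV
#'
#' The on-disk wave format has columns `frame` (1-based index), `time_s`,
#' and `iph_pct` (IPH as a percentage of image height, 0-100).
#'
#' @param wave A [blink_wave()].
#' @param path File path.
#' @return `write_wave_csv` returns `path` invisibly; `read_wave_csv`
#'   returns a [blink_wave()].
#' @export
write_wave_csv <- function(wave, path) {
  stopifnot(inherits(wave, "blink_wave"))
  df <- data.frame(frame = seq_along(wave), time_s = time_s(wave),
                   iph_pct = 100 * as.numeric(wave))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wave_csv
#' @param fps Frame rate; when `NULL` it is inferred from the `time_s`
#'   column.
#' @export
read_wave_csv <- function(path, fps = NULL) {
  df <- read.csv(path)
  if (!all(c("frame", "iph_pct") %in% names(df)))
    stopf("wave CSV needs columns frame, iph_pct")
  if (is.null(fps)) {
    if (!"time_s" %in% names(df) || nrow(df) < 2)
      stopf("fps not supplied and not inferable from the CSV")
    dt <- diff(df$time_s[1:2])
    if (dt <= 0) stopf("non-increasing time axis")
    fps <- 1 / dt
  }
  blink_wave(df$iph_pct[order(df$frame)] / 100, fps)
}

#' Read and write masks and frames as PNG
#'
#' Masks are written as 0/255 grayscale PNGs; frames as 8-bit grayscale.
#'
#' @param mask,image Matrix to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a matrix (masks
#'   as 0/1, frames in `[0, 1]`).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1
}

#' @rdname write_mask_png
#' @export
write_frame_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_frame_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write and read a synthetic recording spec as YAML
#'
#' @param spec A [synth_spec()].
#' @param path File path.
#' @return `write_synth_spec` returns `path` invisibly; `read_synth_spec`
#'   returns a [synth_spec()].
#' @export
write_synth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  lst <- unclass(spec)
  lst$events <- lapply(spec$events, function(e)
    unclass(e)[c("onset_s", "closing_s", "closed_s", "opening_s",
                 "trough_frac")])
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  events <- lapply(lst$events, function(e)
    blink_event_spec(e$onset_s, e$closing_s, e$closed_s, e$opening_s,
                     e$trough_frac))
  synth_spec(duration_s = lst$duration_s, fps = lst$fps,
             baseline_iph_frac = lst$baseline_iph_frac, events = events,
             wave_noise_sd = lst$wave_noise_sd,
             pixel_noise_sd = lst$pixel_noise_sd, image_w = lst$image_w,
             image_h = lst$image_h,
             max_aperture_frac = lst$max_aperture_frac, seed = lst$seed)
}
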