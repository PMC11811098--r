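# Synthetic eye rendering. The interpalpebral aperture is the region
# between two parabolic arcs sharing fixed canthi; the lower arc is fixed
# and eyelid closure moves the upper arc down, so the vertical gap at
# column x is aperture * s(x) with s the shared arc shape (s = 1 at the
# eye's center). A pixel is foreground when its center lies strictly
# between the arcs, which makes the maximum column extent track
# round(iph_frac * image_h) within one pixel and yields an empty mask at
# full closure.

eye_geometry <- function(spec) {
  w <- spec$image_w; h <- spec$image_h
  x0 <- 0.08 * w; x1 <- 0.92 * w
  xs <- (seq_len(w) - 0.5)
  s <- 4 * (xs - x0) * (x1 - xs) / (x1 - x0)^2
  s[s < 0] <- 0
  list(s = s, yc = 0.5 * h,
       lower_amp = 0.45 * spec$max_aperture_frac * h)
}

#' Render one synthetic eye frame and its exact mask
#'
#' Draws a single grayscale frame of the synthetic eye at a given aperture
#' and returns it together with the exact binary mask of the rendered
#' interpalpebral region. Pixel noise (sd `spec$pixel_noise_sd`, 8-bit gray
#' levels) is added to the image only; the mask is always exact.
#'
#' @param iph_frac Aperture height as a fraction of image height, in
#'   `[0, max_aperture_frac]`.
#' @param spec A [synth_spec()] providing geometry and noise level.
#' @param seed Integer seed for the pixel noise.
#' @return List with `image` (h x w matrix in `[0, 1]`) and `mask`
#'   (h x w 0/1 matrix). The maximum column-wise vertical extent of the mask
#'   equals `round(iph_frac * image_h)` within one pixel; `iph_frac = 0`
#'   gives an empty mask.
#' @examples
#' fr <- render_frame(0.2, synth_spec(image_w = 160, image_h = 120), seed = 1)
#' max(colSums(fr$mask)) # about 24 = 0.2 * 120
#' @export
render_frame <- function(iph_frac, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (iph_frac < 0) stopf("iph_frac must be >= 0")
  if (iph_frac > spec$max_aperture_frac)
    stopf("iph_frac %.3f exceeds the geometric maximum aperture %.3f",
          iph_frac, spec$max_aperture_frac)
  g <- eye_geometry(spec)
  h <- spec$image_h; w <- spec$image_w
  A <- iph_frac * h
  y_low <- g$yc + g$lower_amp * g$s          # per column
  y_up <- y_low - A * g$s
  rc <- seq_len(h) - 0.5                     # pixel-center rows
  mask <- (outer(rc, y_up, `>`) & outer(rc, y_low, `<`)) * 1
  img <- matrix(0.35, h, w)                  # skin background
  # lid shading: darken a band just outside each arc
  band <- (outer(rc, y_low, `>=`) & outer(rc, y_low + 6, `<`)) |
    (outer(rc, y_up - 6, `>`) & outer(rc, y_up, `<=`))
  img[band & outer(rep(TRUE, h), g$s > 0)] <- 0.28
  img[mask == 1] <- 0.85                     # sclera
  if (A > 0) {                               # iris/pupil disk
    xc <- w / 2
    rad <- 0.11 * h
    iris <- outer((rc - g$yc)^2, (seq_len(w) - 0.5 - xc)^2, `+`) <= rad^2
    img[iris & mask == 1] <- 0.2
  }
  if (spec$pixel_noise_sd > 0) {
    img <- with_seed(seed,
                     img + matrix(rnorm(h * w, 0, spec$pixel_noise_sd / 255),
                                  h, w))
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, mask = mask)
}

#' Synthesize a full frame/mask video with ground truth
#'
#' Renders one frame and one exact mask per sample of the noise-free blink
#' wave of `spec`. Pixel noise is added to the frames only, so the masks and
#' the ground truth remain exact regardless of noise settings.
#'
#' @param spec A [synth_spec()]. Frame count is
#'   `round(duration_s * fps)`; memory grows accordingly, so keep
#'   `image_w`/`image_h`/`duration_s` modest when materializing in RAM (use
#'   [generate_dataset()] to stream frames to disk instead).
#' @return List with `frames` (list of h x w matrices), `masks` (list of 0/1
#'   matrices), `wave` (the noisy [blink_wave()] implied by the spec) and
#'   `truth` as in [synthesize_wave()].
#' @seealso [generate_dataset()] for the on-disk equivalent.
#' @export
synthesize_video <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sw <- synthesize_wave(spec)
  n <- length(sw$truth$iph_frac)
  seeds <- derive_seeds(spec$seed, n)
  frames <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- render_frame(sw$truth$iph_frac[i], spec, seed = seeds[i])
    frames[[i]] <- fr$image
    masks[[i]] <- fr$mask
  }
  list(frames = frames, masks = masks, wave = sw$wave, truth = sw$truth)
}
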