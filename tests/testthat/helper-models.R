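# Small trained models shared across test files (trained once per run).
.model_cache <- new.env(parent = emptyenv())

tiny_spec <- function(seed = 2) {
  synth_spec(image_w = 96, image_h = 72, pixel_noise_sd = 5,
             baseline_iph_frac = 0.35, max_aperture_frac = 0.5, seed = seed)
}

tiny_cls_model <- function() {
  if (!is.null(.model_cache$cls)) return(.model_cache$cls)
  spec <- tiny_spec()
  set.seed(11)
  n <- 120
  iphs <- ifelse(runif(n) < 0.4, 0, runif(n, 0.03, 0.5))
  frames <- lapply(seq_len(n), function(i)
    render_frame(iphs[i], spec, seed = 400 + i)$image)
  states <- ifelse(iphs == 0, "disappearance", "existence")
  cfg <- cls_config(input_size = 32, patch = 4, embed = 16,
                    depths = c(1, 1, 1, 1), heads = c(2, 2, 2, 2),
                    window = 2, epochs = 6, seed = 5)
  .model_cache$cls_states <- states
  .model_cache$cls_frames <- frames
  .model_cache$cls <- train_classifier(frames, states, cfg)
  .model_cache$cls
}

tiny_seg_model <- function() {
  if (!is.null(.model_cache$seg)) return(.model_cache$seg)
  vid <- make_seg_video(48, fps = 20, image_w = 96, image_h = 72, seed = 8,
                        mix = 0, closed_range = c(0.25, 0.4))
  cfg <- seg_config(input_size = 64, base_width = 8, epochs = 12,
                    patience = 12, lr = 0.1, seed = 4)
  .model_cache$seg <- train_segmentation(vid$frames, vid$masks, cfg)
  .model_cache$seg
}
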