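# Shared fixtures: reduced-size phantom geometries and datasets used across
# the suite so training-dependent checks run in minutes on one CPU. The
# radial pixel pitch (5 um), tissue appearance and guidewire/lesion
# geometry follow the full-size generator defaults.

small_phantom_config <- function(seed, n_frames = 10, n_alines = 64L,
                                 lesion_arc = c(90, 270), ...) {
  phantom_config(n_frames = n_frames, r_size = 300L, n_alines = n_alines,
                 lumen_radius_range = c(0.35, 0.6),
                 guidewire_width_range = c(4L, 10L),
                 lipid_arc_range = lesion_arc, seed = seed, ...)
}

tiny_phantom_config <- function(seed, n_frames = 8) {
  phantom_config(n_frames = n_frames, r_size = 300L, n_alines = 48L,
                 lumen_radius_range = c(0.35, 0.6),
                 guidewire_width_range = c(4L, 8L),
                 lipid_arc_range = c(90, 270), seed = seed)
}

# Preprocessed frame/mask dataset from a batch of phantom pullbacks.
make_phantom_dataset <- function(seeds, cfg_fun = small_phantom_config,
                                 depth = 48L, calc = FALSE) {
  xs <- list(); ys <- list()
  for (s in seeds) {
    cfg <- cfg_fun(s)
    gen <- if (calc) generate_calcific_pullback else generate_pullback
    sim <- gen(cfg)
    pp <- preprocess_pullback(sim$pullback, depth = depth,
                              guidewire_width_range =
                                cfg$guidewire_width_range)
    pm <- preprocess_mask(sim$truth$fc_mask_raw, pp$shifts, depth)
    for (f in seq_len(cfg$n_frames)) {
      xs[[length(xs) + 1L]] <- pp$pullback$frames[, , f]
      ys[[length(ys) + 1L]] <- pm[, , f] * 1
    }
  }
  list(x = xs, y = ys)
}

random_mask <- function(h = 48, w = 48, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# Benchmark model configs
small_model_config <- function() {
  seg_model_config(init_filters = 8L, n_levels = 3L, dropout_rate = 0.2)
}

tiny_model_config <- function() {
  seg_model_config(init_filters = 4L, n_levels = 3L, dropout_rate = 0.2,
                   norm_groups = 4L)
}
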