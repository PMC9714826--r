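# Small phantom fixtures and micro pipeline configurations used across the
# unit tests. Everything is generated in code from fixed seeds.

tiny_phantom_spec <- function(seed = 1L, delta = 15, n_slices = 3,
                              side = "left", theta = 3, tx = 2, ty = -1) {
  phantom_spec(n_slices = n_slices, image_shape = c(48, 48),
               brain_semiaxes = c(19, 15), skull_thickness = 2,
               lesion_side = side,
               lesion_center = c(23.5, if (side == "left") 15 else 32),
               lesion_radius = 6, lesion_slices = c(1, n_slices),
               delta = delta, label_shape = c(48, 40),
               theta = theta, tx = tx, ty = ty, seed = seed)
}

tiny_case <- function(seed = 1L, ...) {
  generate_phantom(tiny_phantom_spec(seed = seed, ...))
}

micro_config <- function(...) {
  pipeline_config(features = feature_config(cell_size = 8, scales = c(8, 16)),
                  extractor_epochs = 3, extractor_sample_frac = 1,
                  ensemble_epochs = 3, ensemble_sample_frac = 1,
                  f4_epochs = 10, cell_size = 16, ...)
}

# deterministic random binary masks for metric oracles
random_mask <- function(seed, H = 48, W = 48, p = 0.2) {
  set.seed(seed)
  matrix(as.integer(runif(H * W) < p), H, W)
}
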