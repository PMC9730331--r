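# small phantom builders shared across tests (kept small for speed)

small_spec <- function(..., seed = 11L) {
  phantom_spec(grid_shape = c(48, 48, 8), voxel_size = c(0.8, 0.8),
               gland_semiaxes = c(14, 11, 13), seed = seed, ...)
}

small_phantom <- function(..., seed = 11L) {
  generate_phantom(small_spec(..., seed = seed))
}

# phantom with one centred lesion of given semiaxes (cm) and slice count
lesion_phantom <- function(semiaxes = c(0.5, 0.3), n_slices = 1,
                           orientation = 0, noise_sigma = 0, seed = 11L) {
  sp <- small_spec(
    lesions = list(lesion_spec(c(24, 24, 4), semiaxes,
                               orientation = orientation,
                               n_slices = n_slices)),
    noise_sigma = noise_sigma, seed = seed)
  generate_phantom(sp)
}

# exact boundary points of an ellipse (cm), optionally rotated/translated
ellipse_points <- function(a, b, n = 100, rot = 0, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(x * cos(rot) - y * sin(rot) + center[1],
        x * sin(rot) + y * cos(rot) + center[2])
}

# family of phantoms with jittered zone split, as atlas training subjects
atlas_family <- function(n = 4, base_split = 0.4, jitter = 0.03,
                         seed = 21L) {
  set.seed(seed)
  splits <- base_split + stats::runif(n, -jitter, jitter)
  lapply(seq_len(n), function(i) {
    ph <- small_phantom(zone_split = splits[i], seed = 100L + i)
    list(volume = ph$volumes$dwi, pz = ph$pz_truth, tz = ph$tz_truth,
         phantom = ph)
  })
}
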