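# Shared small fixtures. Phantoms are kept compact so the whole suite stays
# fast; geometric parameters are scaled with the in-plane shape.

small_phantom_config <- function(...) {
  phantom_config(roi_radius = 2.2, ring_radius = 6.5, ...)
}

small_phantom <- function(seed = 1L, f = 0.05, n_slices = 10, ...) {
  generate_phantom(n_slices = n_slices, in_plane_shape = c(48, 32),
                   seed = seed, config = small_phantom_config(f = f, ...))
}

# A single-voxel dataset wrapping one signal vector.
one_voxel_dataset <- function(signal, scheme) {
  dwi_dataset(array(signal, c(1, 1, 1, length(signal))), scheme)
}

# Per-muscle mean of a map over the un-eroded label mask.
per_muscle_mean <- function(map, labels) {
  vapply(1:14, function(l) mean(map[labels == l]), numeric(1))
}

# A synthetic cohort record table with prescribed SNR values, mimicking the
# bookkeeping of a 15-subject bilateral study (420 records).
bookkeeping_fixture <- function(n_subjects = 15, low_snr_pairs = 25) {
  lab <- muscle_label_map()
  grid <- expand.grid(subject = seq_len(n_subjects), session = 1:2,
                      code = lab$code, stringsAsFactors = FALSE)
  grid$snr <- 45
  # mark whole subject x muscle pairs as low-SNR (both sessions below 20)
  pairs <- unique(grid[, c("subject", "code")])
  drop <- pairs[seq_len(low_snr_pairs), ]
  key <- interaction(grid$subject, grid$code)
  dropkey <- interaction(drop$subject, drop$code)
  grid$snr[key %in% dropkey] <- 12
  grid$included <- grid$snr >= 20
  grid
}
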