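# Shared fixture builders for the test suite. All fixtures are generated in
# code under fixed seeds.

# Quiet noise model for noiseless rendering checks.
noiseless <- function(background = 0) {
  noise_model(background_level = background, read_noise_sd = 0,
              shot_noise = FALSE)
}

# Default "fixture" camera noise used across detection/localization tests:
# moderate autofluorescence background and sCMOS-like read noise.
fixture_noise <- function() noise_model()  # bg 50, read 5, shot on

# A narrow-PSF emitter whose 5-px aperture capture is ~99.6%, for tests that
# compare aperture sums against total emitted counts.
narrow_emitter <- function(...) {
  emitter_model(psf_sigma = 1.5 * 0.053, brightness_cv = 0, bleach_rate = 0,
                ...)
}

# Render one frame containing a single spot of given integrated intensity.
render_single_spot <- function(total, x_um, y_um, dim_px = c(32, 32),
                               psf_sigma = 0.130, pixel_size = 0.053,
                               background = 0) {
  img <- matrix(background, dim_px[1], dim_px[2])
  slimspt:::render_spot(img, x_um, y_um, total, psf_sigma, pixel_size)
}

# Digitized ball mask: physical radius r (um) on a voxel grid.
ball_mask <- function(r_um, dim_vox, voxel = c(1, 1, 1)) {
  a <- array(FALSE, dim_vox)
  ctr <- (dim_vox + 1) / 2
  idx <- which(array(TRUE, dim_vox), arr.ind = TRUE)
  rho <- sqrt(((idx[, 1] - ctr[1]) * voxel[1])^2 +
                ((idx[, 2] - ctr[2]) * voxel[2])^2 +
                ((idx[, 3] - ctr[3]) * voxel[3])^2)
  a[idx[rho <= r_um, , drop = FALSE]] <- TRUE
  a
}

# Brownian track table with localization noise, for mobility tests.
sim_brownian_tracks <- function(n, D, len, dt = 0.0125, sigma_loc = 0.04,
                                seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(track_id = i, frame = seq_len(len),
               x_um = cumsum(c(0, stats::rnorm(len - 1, 0, sqrt(2 * D * dt)))) +
                 stats::rnorm(len, 0, sigma_loc),
               y_um = cumsum(c(0, stats::rnorm(len - 1, 0, sqrt(2 * D * dt)))) +
                 stats::rnorm(len, 0, sigma_loc))
  }))
}
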