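#' Movie calibration
#'
#' Physical calibration of a single-plane time-lapse acquisition. Defaults
#' match an oversampled Slimfield/SlimVar camera geometry: 53 nm pixels,
#' 12.5 ms frame interval (80 Hz), and a 240 x 184 px analysis crop
#' (12.7 x 9.8 um).
#'
#' @param pixel_size Pixel edge length in um (default 0.053).
#' @param frame_interval Frame interval in seconds (default 0.0125).
#' @param frame_count Number of frames.
#' @param roi Integer c(width, height) of the field in pixels.
#' @return An object of class `movie_calibration`.
#' @export
movie_calibration <- function(pixel_size = 0.053, frame_interval = 0.0125,
                              frame_count = 100L, roi = c(240L, 184L)) {
  stopifnot_positive(pixel_size, "pixel_size")
  stopifnot_positive(frame_interval, "frame_interval")
  stopifnot_positive(frame_count, "frame_count")
  roi <- as.integer(roi)
  if (length(roi) != 2L || any(roi < 16L)) {
    stop("parameter error: `roi` must be two integers >= 16", call. = FALSE)
  }
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 frame_count = as.integer(frame_count), roi = roi),
            class = "movie_calibration")
}

#' Fluorophore emitter model
#'
#' Per-molecule brightness, its spread, photobleaching kinetics and PSF width
#' for the synthetic imaging model. The default brightness of 110 counts per
#' molecule per frame with 15 counts s.d. corresponds to an mScarlet-I-class
#' reporter; the PSF sigma of 0.130 um (about 2.5 px at 53 nm pixels) makes a
#' focus span a 5 px photometry aperture.
#'
#' @param brightness_b Mean integrated counts per molecule per frame.
#' @param brightness_cv Coefficient of variation of per-molecule brightness.
#' @param bleach_rate Per-fluorophore bleach rate (1/frames).
#' @param psf_sigma PSF Gaussian sigma in um.
#' @param maturation_fraction Fraction of fluorophores that are bright.
#' @return An object of class `emitter_model`.
#' @export
emitter_model <- function(brightness_b = 110, brightness_cv = 15 / 110,
                          bleach_rate = 0.02, psf_sigma = 0.130,
                          maturation_fraction = 1) {
  stopifnot_positive(brightness_b, "brightness_b")
  stopifnot_nonneg(brightness_cv, "brightness_cv")
  stopifnot_nonneg(bleach_rate, "bleach_rate")
  stopifnot_positive(psf_sigma, "psf_sigma")
  if (maturation_fraction < 0 || maturation_fraction > 1) {
    stop("parameter error: `maturation_fraction` must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(brightness_b = brightness_b, brightness_cv = brightness_cv,
                 bleach_rate = bleach_rate, psf_sigma = psf_sigma,
                 maturation_fraction = maturation_fraction),
            class = "emitter_model")
}

#' Camera and illumination noise model
#'
#' Counts are modelled as Poisson(signal + background) plus Gaussian read
#' noise at unit gain. The illumination profile is either flat or a centred
#' 2D Gaussian whose value at the ROI corner equals `min_fraction` of the
#' peak, emulating an effectively uniform illumination crop (default 0.8,
#' i.e. 80% of peak at the field edge).
#'
#' @param background_level Mean background in counts/pixel/frame.
#' @param read_noise_sd Gaussian read noise s.d. in counts.
#' @param shot_noise Apply Poisson shot noise?
#' @param illumination "flat" or "gaussian".
#' @param min_fraction For "gaussian": illumination at the ROI corner as a
#'   fraction of the peak, in (0, 1].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_level = 50, read_noise_sd = 5,
                        shot_noise = TRUE, illumination = c("flat", "gaussian"),
                        min_fraction = 0.8) {
  stopifnot_nonneg(background_level, "background_level")
  stopifnot_nonneg(read_noise_sd, "read_noise_sd")
  illumination <- match.arg(illumination)
  if (illumination == "gaussian" && (min_fraction <= 0 || min_fraction > 1)) {
    stop("parameter error: `min_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(background_level = background_level,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 illumination = illumination, min_fraction = min_fraction),
            class = "noise_model")
}

#' 3D two-channel phantom configuration
#'
#' Describes ellipsoidal objects rendered into a two-channel confocal-like
#' stack. Default voxel calibration is 0.06 x 0.06 x 0.26 um (xyz).
#'
#' @param voxel_size Numeric c(x, y, z) voxel edges in um.
#' @param shape Integer c(nx, ny, nz) stack dimensions in voxels.
#' @param objects_ch1,objects_ch2 Data frames with columns x, y, z (centre,
#'   um), rx, ry, rz (radii, um) and peak (peak intensity, counts). NULL or
#'   zero rows for an empty channel.
#' @param channel_shift Lateral chromatic offset c(dx, dy) in um applied to
#'   channel 2.
#' @param background Background counts added to both channels.
#' @param seed Integer seed for the rendering noise.
#' @return An object of class `phantom3d_config`.
#' @export
phantom3d_config <- function(voxel_size = c(0.06, 0.06, 0.26),
                             shape = c(64L, 64L, 16L),
                             objects_ch1 = NULL, objects_ch2 = NULL,
                             channel_shift = c(0, 0), background = 0,
                             seed = 1L) {
  stopifnot_positive(voxel_size, "voxel_size")
  shape <- as.integer(shape)
  stopifnot_positive(shape, "shape")
  chk <- function(df, nm) {
    if (is.null(df)) return(data.frame(x = numeric(0), y = numeric(0),
                                       z = numeric(0), rx = numeric(0),
                                       ry = numeric(0), rz = numeric(0),
                                       peak = numeric(0)))
    need <- c("x", "y", "z", "rx", "ry", "rz", "peak")
    if (!all(need %in% names(df))) {
      stop(sprintf("parameter error: `%s` needs columns %s", nm,
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    if (nrow(df) && any(df$rx <= 0 | df$ry <= 0 | df$rz <= 0)) {
      stop("parameter error: object radii must be positive", call. = FALSE)
    }
    df
  }
  structure(list(voxel_size = voxel_size, shape = shape,
                 objects_ch1 = chk(objects_ch1, "objects_ch1"),
                 objects_ch2 = chk(objects_ch2, "objects_ch2"),
                 channel_shift = channel_shift, background = background,
                 seed = as.integer(seed)),
            class = "phantom3d_config")
}

#' Aperture photometry and sifting configuration
#'
#' Focus intensity is the sum of pixel values within `signal_radius` of the
#' focus centre minus the per-pixel mean of the remainder of a square of
#' half-width `background_box_halfwidth` (default: a 5 px radius disc inside
#' a 17 px square). SNR is the mean background-corrected aperture intensity
#' per disc pixel divided by the robust s.d. of the background region.
#'
#' @param signal_radius Disc radius in pixels (default 5).
#' @param background_box_halfwidth Half-width of the background square in
#'   pixels (default 8, i.e. a 17 px square).
#' @param snr_threshold Minimum SNR per pixel, in background-s.d. units.
#' @param min_separation Minimum separation between accepted foci (pixels);
#'   candidate pairs closer than this are both discarded as ambiguous.
#' @return An object of class `aperture_config`.
#' @export
aperture_config <- function(signal_radius = 5L, background_box_halfwidth = 8L,
                            snr_threshold = 0.4, min_separation = 5) {
  if (signal_radius >= background_box_halfwidth) {
    stop("parameter error: `signal_radius` must be < `background_box_halfwidth`",
         call. = FALSE)
  }
  stopifnot_positive(snr_threshold, "snr_threshold")
  stopifnot_positive(min_separation, "min_separation")
  structure(list(signal_radius = as.integer(signal_radius),
                 background_box_halfwidth = as.integer(background_box_halfwidth),
                 snr_threshold = snr_threshold, min_separation = min_separation),
            class = "aperture_config")
}

#' Track linking configuration
#'
#' @param max_displacement Maximum frame-to-frame displacement in um (the
#'   budget over a gap of g skipped frames scales by sqrt(g + 1)).
#' @param max_gap Maximum number of skipped frames bridged within a track.
#' @param min_track_length Minimum number of foci per reported track
#'   (default 3, so the MSD has at least two lag points).
#' @return An object of class `linking_config`.
#' @export
linking_config <- function(max_displacement = 0.45, max_gap = 1L,
                           min_track_length = 3L) {
  stopifnot_positive(max_displacement, "max_displacement")
  stopifnot_nonneg(max_gap, "max_gap")
  stopifnot_positive(min_track_length, "min_track_length")
  structure(list(max_displacement = max_displacement,
                 max_gap = as.integer(max_gap),
                 min_track_length = as.integer(min_track_length)),
            class = "linking_config")
}

#' Stoichiometry extrapolation configuration
#'
#' @param n_initial_frames Number of initial track frames used for the
#'   linear extrapolation of initial intensity (default 5).
#' @return An object of class `stoich_config`.
#' @export
stoich_config <- function(n_initial_frames = 5L) {
  if (n_initial_frames < 2L) {
    stop("parameter error: `n_initial_frames` must be >= 2", call. = FALSE)
  }
  structure(list(n_initial_frames = as.integer(n_initial_frames),
                 extrapolation = "linear-fit-to-first-frame"),
            class = "stoich_config")
}

#' Periodicity analysis configuration
#'
#' @param kernel_sd Fixed Gaussian KDE bandwidth in molecules (default 0.6,
#'   the empirical measurement s.d. on the single-molecule brightness scale).
#' @param grid_step Stoichiometry grid step in molecules.
#' @param max_s Upper end of the stoichiometry grid; NULL extends to the data.
#' @param peak_prominence_fraction Minimum peak prominence as a fraction of
#'   the global density maximum.
#' @return An object of class `periodicity_config`.
#' @export
periodicity_config <- function(kernel_sd = 0.6, grid_step = 0.05, max_s = NULL,
                               peak_prominence_fraction = 0.05) {
  stopifnot_positive(kernel_sd, "kernel_sd")
  stopifnot_positive(grid_step, "grid_step")
  stopifnot_nonneg(peak_prominence_fraction, "peak_prominence_fraction")
  structure(list(kernel_sd = kernel_sd, grid_step = grid_step, max_s = max_s,
                 peak_prominence_fraction = peak_prominence_fraction),
            class = "periodicity_config")
}

#' Blob-finder segmentation parameters
#'
#' Channel-specific presets follow the confocal analyses: mScarlet-I condensed
#' foci at diameter 0.35 um / probability threshold 45% / split sensitivity
#' 50%; mTurquoise at 0.3 um / 37% / 50%; eYFP at 0.35 um / 37% / 50%.
#'
#' @param diameter Expected object diameter in um.
#' @param probability_threshold Seed acceptance threshold in percent of the
#'   maximum normalized blob response.
#' @param split_sensitivity Watershed split sensitivity in percent; 0 merges
#'   all touching basins, 100 never merges.
#' @param preset Optional named preset: "mscarlet", "mturquoise", "eyfp".
#' @return An object of class `blob_params`.
#' @export
blob_params <- function(diameter = 0.35, probability_threshold = 45,
                        split_sensitivity = 50, preset = NULL) {
  if (!is.null(preset)) {
    p <- switch(match.arg(preset, c("mscarlet", "mturquoise", "eyfp")),
                mscarlet = c(0.35, 45, 50),
                mturquoise = c(0.30, 37, 50),
                eyfp = c(0.35, 37, 50))
    diameter <- p[1]; probability_threshold <- p[2]; split_sensitivity <- p[3]
  }
  stopifnot_positive(diameter, "diameter")
  if (probability_threshold < 0 || probability_threshold > 100 ||
      split_sensitivity < 0 || split_sensitivity > 100) {
    stop("parameter error: thresholds must lie in [0, 100]", call. = FALSE)
  }
  structure(list(diameter = diameter,
                 probability_threshold = probability_threshold,
                 split_sensitivity = split_sensitivity),
            class = "blob_params")
}

#' Object volume and sphericity filters
#'
#' @param min_volume Minimum object volume in um^3 (default 0.03).
#' @param min_sphericity Minimum mesh (Wadell) sphericity (default 0.6).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_volume = 0.03, min_sphericity = 0.6) {
  stopifnot_nonneg(min_volume, "min_volume")
  if (min_sphericity <= 0 || min_sphericity > 1) {
    stop("parameter error: `min_sphericity` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(min_volume = min_volume, min_sphericity = min_sphericity),
            class = "filter_params")
}
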