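# Synthetic movie / bleach-trace / 3D-stack generator with exact ground truth.
#
# The imaging model: each assembly of stoichiometry S carries S fluorophores
# with per-fluorophore brightness ~ Normal(b, cv*b) counts/frame, independent
# exponential photobleaching, and diffuses as a 2D Brownian walk with
# reflecting ROI boundaries. Fluorescence is rendered as a pixel-integrated
# 2D Gaussian PSF (truncated at 4 sigma); the camera adds Poisson shot noise
# and Gaussian read noise at unit gain.

# Illumination factor at a position (um). Gaussian profile is centred on the
# ROI and reaches `min_fraction` of peak at the ROI corner.
illumination_factor <- function(x_um, y_um, calibration, noise) {
  if (noise$illumination == "flat") return(rep(1, length(x_um)))
  w <- calibration$roi[1] * calibration$pixel_size
  h <- calibration$roi[2] * calibration$pixel_size
  r2max <- (w / 2)^2 + (h / 2)^2
  if (noise$min_fraction >= 1) return(rep(1, length(x_um)))
  s2 <- r2max / (2 * log(1 / noise$min_fraction))
  r2 <- (x_um - w / 2)^2 + (y_um - h / 2)^2
  exp(-r2 / (2 * s2))
}

# Add a pixel-integrated Gaussian spot to an image (rows = y, cols = x).
# `total` is the integrated spot intensity in counts.
render_spot <- function(img, x_um, y_um, total, psf_sigma, pixel_size,
                        truncate = 4) {
  if (total <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  r_px <- ceiling(truncate * psf_sigma / pixel_size)
  jc <- floor(x_um / pixel_size) + 1L
  ic <- floor(y_um / pixel_size) + 1L
  j0 <- max(1L, jc - r_px); j1 <- min(nc, jc + r_px)
  i0 <- max(1L, ic - r_px); i1 <- min(nr, ic + r_px)
  if (j0 > j1 || i0 > i1) return(img)
  ex <- pixel_size * ((j0 - 1L):j1)  # pixel edges along x
  ey <- pixel_size * ((i0 - 1L):i1)
  wx <- diff(stats::pnorm(ex, mean = x_um, sd = psf_sigma))
  wy <- diff(stats::pnorm(ey, mean = y_um, sd = psf_sigma))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + total * outer(wy, wx)
  img
}

# Reflect positions into [0, L].
reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate a single-plane tracking movie with ground truth
#'
#' Renders Brownian assemblies of known stoichiometry and diffusion
#' coefficient into a calibrated time-lapse movie, returning the movie and
#' the exact latent truth (per-frame positions, live-fluorophore counts and
#' noise-free expected intensities).
#'
#' @param calibration A [movie_calibration()].
#' @param assemblies Data frame with one row per assembly: columns `S`
#'   (integer stoichiometry >= 1), `D` (um^2/s) and optionally `x0`, `y0`
#'   (initial position, um; uniform in the ROI when absent). A zero-row data
#'   frame yields a background-only movie.
#' @param emitter An [emitter_model()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for trajectories, brightness and bleaching.
#' @param noise_seed Optional separate seed for camera noise; defaults to
#'   `seed + 1` so truth is reproducible independently of the photon noise.
#' @param render If FALSE, skip rendering and return `movie = NULL` (useful
#'   when only the latent trajectories are needed).
#' @return List with elements `movie` (array height x width x frames, counts),
#'   `truth` (data frame: id, frame, x_um, y_um, n_live, expected_intensity),
#'   `assemblies` (per-assembly truth incl. bleach frames), and the three
#'   configuration objects.
#' @export
simulate_movie <- function(calibration, assemblies, emitter, noise, seed,
                           noise_seed = NULL, render = TRUE) {
  stopifnot(inherits(calibration, "movie_calibration"),
            inherits(emitter, "emitter_model"),
            inherits(noise, "noise_model"))
  if (is.null(assemblies)) {
    assemblies <- data.frame(S = integer(0), D = numeric(0))
  }
  if (nrow(assemblies) && (any(assemblies$S < 1) || any(assemblies$D < 0))) {
    stop("parameter error: assembly S must be >= 1 and D >= 0", call. = FALSE)
  }
  px <- calibration$pixel_size
  W <- calibration$roi[1] * px
  H <- calibration$roi[2] * px
  Tn <- calibration$frame_count
  nA <- nrow(assemblies)

  set.seed(seed)
  truth_list <- vector("list", nA)
  ass_out <- vector("list", nA)
  for (a in seq_len(nA)) {
    S <- as.integer(assemblies$S[a])
    D <- assemblies$D[a]
    x0 <- if ("x0" %in% names(assemblies) && !is.na(assemblies$x0[a]))
      assemblies$x0[a] else stats::runif(1, 0, W)
    y0 <- if ("y0" %in% names(assemblies) && !is.na(assemblies$y0[a]))
      assemblies$y0[a] else stats::runif(1, 0, H)
    step_sd <- sqrt(2 * D * calibration$frame_interval)
    x <- reflect_into(x0 + c(0, cumsum(stats::rnorm(Tn - 1, 0, step_sd))), W)
    y <- reflect_into(y0 + c(0, cumsum(stats::rnorm(Tn - 1, 0, step_sd))), H)
    bright <- pmax(0, stats::rnorm(S, emitter$brightness_b,
                                   emitter$brightness_cv * emitter$brightness_b))
    mature <- stats::runif(S) < emitter$maturation_fraction
    # fluorophore f is live during 0-based frames 0..g_f (g ~ Geometric)
    p_bleach <- 1 - exp(-emitter$bleach_rate)
    g <- if (p_bleach > 0) stats::rgeom(S, p_bleach) else rep(Inf, S)
    tt <- 0:(Tn - 1)
    live_mat <- outer(g, tt, ">=") & mature      # S x Tn
    n_live <- colSums(live_mat)
    expected <- colSums(live_mat * bright) *
      illumination_factor(x, y, calibration, noise)
    truth_list[[a]] <- data.frame(id = a, frame = seq_len(Tn), x_um = x,
                                  y_um = y, n_live = n_live,
                                  expected_intensity = expected)
    ass_out[[a]] <- data.frame(id = a, S = S, D = D, x0 = x[1], y0 = y[1],
                               bleach_frames = I(list(ifelse(is.finite(g),
                                                             g + 1, NA))))
  }
  truth <- if (nA) do.call(rbind, truth_list) else
    data.frame(id = integer(0), frame = integer(0), x_um = numeric(0),
               y_um = numeric(0), n_live = integer(0),
               expected_intensity = numeric(0))

  if (!render) {
    return(list(movie = NULL, truth = truth,
                assemblies = if (nA) do.call(rbind, ass_out) else
                  data.frame(id = integer(0), S = integer(0), D = numeric(0)),
                calibration = calibration, emitter = emitter, noise = noise,
                seed = seed))
  }
  movie <- array(0, dim = c(calibration$roi[2], calibration$roi[1], Tn))
  for (f in seq_len(Tn)) {
    img <- matrix(0, calibration$roi[2], calibration$roi[1])
    if (nA) {
      tf <- truth[truth$frame == f, ]
      for (r in seq_len(nrow(tf))) {
        img <- render_spot(img, tf$x_um[r], tf$y_um[r],
                           tf$expected_intensity[r], emitter$psf_sigma, px)
      }
    }
    movie[, , f] <- img + noise$background_level
  }
  set.seed(noise_seed %||% (seed + 1L))
  if (noise$shot_noise) {
    movie <- array(stats::rpois(length(movie), pmax(movie, 0)), dim = dim(movie))
  }
  if (noise$read_noise_sd > 0) {
    movie <- movie + array(stats::rnorm(length(movie), 0, noise$read_noise_sd),
                           dim = dim(movie))
  }
  list(movie = movie, truth = truth,
       assemblies = if (nA) do.call(rbind, ass_out) else
         data.frame(id = integer(0), S = integer(0), D = numeric(0)),
       calibration = calibration, emitter = emitter, noise = noise,
       seed = seed)
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Each of `n_fluor` fluorophores carries an independent brightness drawn
#' from the emitter model and bleaches after an exponentially distributed
#' number of frames; the trace is the sum of surviving brightnesses plus
#' Gaussian background noise. The final plateau is zero-mean background.
#'
#' @param n_fluor Number of fluorophores (>= 1).
#' @param emitter An [emitter_model()]; `bleach_rate` must be > 0 for steps
#'   to occur within a finite trace.
#' @param noise_sd Gaussian noise s.d. added to the trace, in counts.
#' @param seed Integer seed.
#' @param n_frames Trace length in frames.
#' @return List with `trace` (numeric), `step_frames` (true bleach frames,
#'   1-based, sorted; the frame is the first frame at which the fluorophore
#'   is dark) and `brightness` (per-fluorophore counts).
#' @export
simulate_bleach_trace <- function(n_fluor, emitter, noise_sd = 0, seed = 1L,
                                  n_frames = 300L) {
  if (n_fluor < 1) stop("parameter error: `n_fluor` must be >= 1", call. = FALSE)
  stopifnot(inherits(emitter, "emitter_model"))
  stopifnot_nonneg(noise_sd, "noise_sd")
  set.seed(seed)
  bright <- pmax(0, stats::rnorm(n_fluor, emitter$brightness_b,
                                 emitter$brightness_cv * emitter$brightness_b))
  p_bleach <- 1 - exp(-emitter$bleach_rate)
  g <- if (p_bleach > 0) stats::rgeom(n_fluor, p_bleach) else
    rep(Inf, n_fluor)
  tt <- 0:(n_frames - 1)
  live <- outer(g, tt, ">=")
  trace <- colSums(live * bright)
  if (noise_sd > 0) trace <- trace + stats::rnorm(n_frames, 0, noise_sd)
  step_frames <- sort(g[is.finite(g) & g + 2 <= n_frames]) + 2
  list(trace = trace, step_frames = as.integer(step_frames),
       brightness = bright)
}

# Ellipsoid membership (normalized radius^2) on the voxel-centre grid of a
# stack stored as [x, y, z]; centre/radii in um.
ellipsoid_rho2 <- function(shape, voxel, centre, radii) {
  cx <- (seq_len(shape[1]) - 0.5) * voxel[1]
  cy <- (seq_len(shape[2]) - 0.5) * voxel[2]
  cz <- (seq_len(shape[3]) - 0.5) * voxel[3]
  dx2 <- ((cx - centre[1]) / radii[1])^2
  dy2 <- ((cy - centre[2]) / radii[2])^2
  dz2 <- ((cz - centre[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Simulate a two-channel 3D confocal-like stack with truth labels
#'
#' Objects are soft-edged ellipsoids: intensity peak * exp(-log(2) * rho^2)
#' where rho is the normalized ellipsoidal radius, so the stated radii are
#' half-maximum radii (object "diameter" = FWHM). Channel 2 objects are
#' rendered displaced by the configured lateral chromatic shift.
#'
#' @param config A [phantom3d_config()].
#' @param noise_sd Optional Gaussian noise s.d. (counts) added to both
#'   channels.
#' @return List with `ch1`, `ch2` (arrays nx x ny x nz, counts), `truth`
#'   (per-object data frame: channel, id, centre, radii, peak, analytic
#'   volume, clipped flag, overlap_fraction with the other channel) and
#'   `config`. If no object fits inside the stack, `warning_empty` is TRUE.
#' @export
simulate_confocal_stack <- function(config, noise_sd = 0) {
  stopifnot(inherits(config, "phantom3d_config"))
  sh <- config$shape; vox <- config$voxel_size
  ext <- sh * vox
  render <- function(objs, shift) {
    a <- array(0, dim = sh)
    masks <- list()
    info <- list()
    for (i in seq_len(nrow(objs))) {
      ctr <- c(objs$x[i] + shift[1], objs$y[i] + shift[2], objs$z[i])
      radii <- c(objs$rx[i], objs$ry[i], objs$rz[i])
      rho2 <- ellipsoid_rho2(sh, vox, ctr, radii)
      a <- a + objs$peak[i] * exp(-log(2) * rho2)
      masks[[i]] <- rho2 <= 1
      clipped <- any(ctr - radii < 0) || any(ctr + radii > ext)
      info[[i]] <- data.frame(id = i, x = ctr[1], y = ctr[2], z = ctr[3],
                              rx = radii[1], ry = radii[2], rz = radii[3],
                              peak = objs$peak[i],
                              volume_analytic = 4 / 3 * pi * prod(radii),
                              clipped = clipped)
    }
    list(img = a + config$background, masks = masks,
         info = if (length(info)) do.call(rbind, info) else NULL)
  }
  ch1 <- render(config$objects_ch1, c(0, 0))
  ch2 <- render(config$objects_ch2, config$channel_shift)
  ov <- function(masks_a, masks_b) {
    vapply(masks_a, function(ma) {
      na <- sum(ma)
      if (na == 0) return(NA_real_)
      inter <- 0L
      for (mb in masks_b) inter <- max(inter, sum(ma & mb))
      # fraction of this object's voxels overlapped by the best-matching
      # object in the other channel
      inter / na
    }, numeric(1))
  }
  truth <- NULL
  if (!is.null(ch1$info)) {
    t1 <- cbind(channel = 1L, ch1$info,
                overlap_fraction = if (length(ch2$masks))
                  ov(ch1$masks, ch2$masks) else
                  rep(0, nrow(ch1$info)))
    truth <- t1
  }
  if (!is.null(ch2$info)) {
    t2 <- cbind(channel = 2L, ch2$info,
                overlap_fraction = if (length(ch1$masks))
                  ov(ch2$masks, ch1$masks) else
                  rep(0, nrow(ch2$info)))
    truth <- if (is.null(truth)) t2 else rbind(truth, t2)
  }
  img1 <- ch1$img; img2 <- ch2$img
  if (noise_sd > 0) {
    set.seed(config$seed)
    img1 <- img1 + array(stats::rnorm(length(img1), 0, noise_sd), dim = sh)
    img2 <- img2 + array(stats::rnorm(length(img2), 0, noise_sd), dim = sh)
  }
  warn_empty <- !is.null(truth) && nrow(truth) > 0 &&
    all(vapply(c(ch1$masks, ch2$masks), sum, numeric(1)) == 0)
  if (isTRUE(warn_empty)) {
    warning("stack too small to contain any object; truth flagged clipped")
  }
  list(ch1 = img1, ch2 = img2, truth = truth, config = config,
       warning_empty = isTRUE(warn_empty))
}

#' Write a movie or 3D stack as multi-page 16-bit TIFF
#'
#' Counts are rounded and clamped to `[0, max_count]` and stored as 16-bit
#' pages (one page per frame or z-slice); [read_tiff_stack()] restores the
#' count scale.
#'
#' @param a 3D array (rows x cols x pages for movies, or x/y/z stacks).
#' @param path Output file.
#' @param max_count Full-scale count value mapped to 16-bit white.
#' @export
write_tiff_stack <- function(a, path, max_count = 65535) {
  pages <- lapply(seq_len(dim(a)[3]), function(k) {
    pmin(pmax(round(a[, , k]), 0), max_count) / max_count
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    out[, , k] <- p * max_count
  }
  out
}

#' Write a simulation to disk (TIFF movie + truth CSV + YAML sidecar)
#'
#' @param sim Result of [simulate_movie()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the artifact files.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, name = "movie") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_tif <- file.path(dir, paste0(name, ".tif"))
  p_csv <- file.path(dir, paste0(name, "_truth.csv"))
  p_yml <- file.path(dir, paste0(name, "_config.yaml"))
  write_tiff_stack(sim$movie, p_tif)
  utils::write.csv(sim$truth, p_csv, row.names = FALSE)
  cfg <- list(seed = sim$seed,
              calibration = unclass(sim$calibration),
              emitter = unclass(sim$emitter),
              noise = unclass(sim$noise))
  yaml::write_yaml(cfg, p_yml)
  invisible(c(p_tif, p_csv, p_yml))
}
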