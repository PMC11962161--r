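# Per-frame focus detection ("sifting"), aperture photometry and iterative
# Gaussian-mask sub-pixel localization.

# Disc / background-region pixel offsets for an aperture, cached per config.
aperture_offsets <- function(config) {
  hw <- config$background_box_halfwidth
  g <- expand.grid(di = -hw:hw, dj = -hw:hw)
  r <- sqrt(g$di^2 + g$dj^2)
  list(disc = g[r <= config$signal_radius, , drop = FALSE],
       bg = g[r > config$signal_radius, , drop = FALSE])
}

#' Aperture intensity of a focus
#'
#' Sums the pixel values within the signal disc around `center` and subtracts
#' the disc-area-scaled mean of the background region (the remainder of the
#' background square). Uniform frames therefore measure exactly zero.
#'
#' @param frame Numeric matrix (rows = y, cols = x), in counts.
#' @param center Integer c(row, col) pixel position of the focus centre.
#' @param config An [aperture_config()].
#' @return Background-corrected aperture intensity in counts.
#' @export
measure_intensity <- function(frame, center, config = aperture_config()) {
  d <- dim(frame)
  i <- as.integer(round(center[1])); j <- as.integer(round(center[2]))
  if (i < 1 || j < 1 || i > d[1] || j > d[2]) {
    stop("center outside frame", call. = FALSE)
  }
  off <- aperture_offsets(config)
  take <- function(o) {
    ii <- i + o$di; jj <- j + o$dj
    keep <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    frame[cbind(ii[keep], jj[keep])]
  }
  disc <- take(off$disc)
  bg <- take(off$bg)
  if (length(bg) == 0) return(sum(disc))
  sum(disc) - length(disc) * mean(bg)
}

# Aperture SNR: mean background-corrected signal per disc pixel over the
# robust (MAD) s.d. of the background region.
aperture_snr <- function(frame, center, config) {
  d <- dim(frame)
  i <- as.integer(round(center[1])); j <- as.integer(round(center[2]))
  off <- aperture_offsets(config)
  ii <- i + off$bg$di; jj <- j + off$bg$dj
  keep <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
  bg <- frame[cbind(ii[keep], jj[keep])]
  s_bg <- stats::mad(bg)
  if (s_bg <= 0) s_bg <- stats::sd(bg)
  if (!is.finite(s_bg) || s_bg <= 0) s_bg <- .Machine$double.eps
  inten <- measure_intensity(frame, center, config)
  ndisc <- nrow(off$disc)
  list(intensity = inten, snr = (inten / ndisc) / s_bg, bg_sd = s_bg)
}

#' Detect candidate foci in a frame
#'
#' Candidates are smoothed local intensity maxima away from the frame border
#' (foci whose background box leaves the frame are discarded), sifted by
#' aperture SNR; pairs of surviving candidates closer than `min_separation`
#' pixels are both discarded as ambiguous overlaps.
#'
#' @param frame Numeric matrix of counts.
#' @param config An [aperture_config()].
#' @param pixel_size Pixel size in um (for reported positions).
#' @param psf_sigma PSF sigma in um, used by the localizer.
#' @param localize If TRUE, refine accepted candidates to sub-pixel
#'   positions.
#' @param detect_sigma Gaussian smoothing (pixels) applied before the local
#'   maximum search.
#' @return Data frame with columns x_um, y_um, row, col, intensity, snr,
#'   precision_um (zero rows when nothing qualifies).
#' @export
detect_foci <- function(frame, config = aperture_config(), pixel_size = 0.053,
                        psf_sigma = 0.130, localize = TRUE,
                        detect_sigma = 1.5) {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), row = integer(0),
                      col = integer(0), intensity = numeric(0),
                      snr = numeric(0), precision_um = numeric(0))
  d <- dim(frame)
  hw <- config$background_box_halfwidth
  if (any(d < 2 * hw + 1)) return(empty)
  sm <- gauss_smooth2(frame, detect_sigma)
  cand <- local_maxima2(sm, margin = hw)
  if (nrow(cand) == 0) return(empty)
  # de-duplicate noise-split maxima of a single focus: within 2.5 px keep
  # only the highest (distinct foci are handled by the ambiguity rule below)
  if (nrow(cand) > 1) {
    o <- order(-sm[cand])
    cand <- cand[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (k in 2:nrow(cand)) {
      prev <- cand[seq_len(k - 1), , drop = FALSE][keep[seq_len(k - 1)], ,
                                                   drop = FALSE]
      dd <- sqrt((prev[, 1] - cand[k, 1])^2 + (prev[, 2] - cand[k, 2])^2)
      if (any(dd <= 2.5)) keep[k] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    m <- aperture_snr(frame, cand[k, ], config)
    if (is.finite(m$snr) && m$snr >= config$snr_threshold && m$intensity > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        row = cand[k, 1], col = cand[k, 2], intensity = m$intensity,
        snr = m$snr, bg_sd = m$bg_sd)
    }
  }
  if (!length(rows)) return(empty)
  acc <- do.call(rbind, rows)
  # ambiguity rule: discard both members of any too-close pair
  if (nrow(acc) > 1) {
    dm <- as.matrix(stats::dist(acc[, c("row", "col")]))
    diag(dm) <- Inf
    acc <- acc[apply(dm, 1, min) >= config$min_separation, , drop = FALSE]
  }
  if (!nrow(acc)) return(empty)
  out <- lapply(seq_len(nrow(acc)), function(k) {
    if (localize) {
      loc <- localize_subpixel(frame, c(acc$row[k], acc$col[k]),
                               config = config, pixel_size = pixel_size,
                               psf_sigma = psf_sigma)
      if (is.null(loc)) return(NULL)
      data.frame(x_um = loc$x_um, y_um = loc$y_um, row = acc$row[k],
                 col = acc$col[k], intensity = acc$intensity[k],
                 snr = acc$snr[k], precision_um = loc$precision_um)
    } else {
      data.frame(x_um = (acc$col[k] - 0.5) * pixel_size,
                 y_um = (acc$row[k] - 0.5) * pixel_size,
                 row = acc$row[k], col = acc$col[k],
                 intensity = acc$intensity[k], snr = acc$snr[k],
                 precision_um = NA_real_)
    }
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Sub-pixel localization by iterative Gaussian-mask centroid
#'
#' Starting from an integer seed pixel, the focus position is refined by
#' iterating a Gaussian-weighted, background-subtracted intensity centroid
#' (pixel-integrated mask, mask sigma = PSF sigma) to convergence. The precision
#' estimate follows the standard centroid-precision formula combining shot
#' noise and background noise (Thompson-style): sigma^2 =
#' (s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2).
#'
#' @param frame Numeric matrix of counts.
#' @param seed_position Integer c(row, col) starting pixel.
#' @param config An [aperture_config()].
#' @param pixel_size Pixel size in um.
#' @param psf_sigma Mask / PSF sigma in um.
#' @param max_iter Maximum number of centroid iterations (the update
#'   contracts toward its fixed point by about a factor 2 per iteration and
#'   stops once the position moves by < 1e-4 px).
#' @return List with x_um, y_um, precision_um, photons; NULL when the net
#'   aperture intensity is non-positive (localization failure).
#' @export
localize_subpixel <- function(frame, seed_position, config = aperture_config(),
                              pixel_size = 0.053, psf_sigma = 0.130,
                              max_iter = 50L) {
  d <- dim(frame)
  i <- as.integer(round(seed_position[1])); j <- as.integer(round(seed_position[2]))
  if (i < 1 || j < 1 || i > d[1] || j > d[2]) {
    stop("seed outside frame", call. = FALSE)
  }
  hw <- config$background_box_halfwidth
  i0 <- max(1L, i - hw); i1 <- min(d[1], i + hw)
  j0 <- max(1L, j - hw); j1 <- min(d[2], j + hw)
  sub <- frame[i0:i1, j0:j1, drop = FALSE]
  # background level and noise from the region outside the signal disc
  off <- aperture_offsets(config)
  ii <- i + off$bg$di; jj <- j + off$bg$dj
  keep <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
  bgpix <- frame[cbind(ii[keep], jj[keep])]
  bg_level <- mean(bgpix)
  bg_sd <- stats::mad(bgpix)
  net <- sub - bg_level
  # pixel-centre coordinates in um
  xs <- ((j0:j1) - 0.5) * pixel_size
  ys <- ((i0:i1) - 0.5) * pixel_size
  cx <- (j - 0.5) * pixel_size
  cy <- (i - 0.5) * pixel_size
  for (it in seq_len(max_iter)) {
    # pixel-integrated mask weights: exact symmetry for foci centred on
    # pixel centres and on pixel corners alike
    ex <- c(xs - pixel_size / 2, xs[length(xs)] + pixel_size / 2)
    ey <- c(ys - pixel_size / 2, ys[length(ys)] + pixel_size / 2)
    wx <- diff(stats::pnorm(ex, cx, psf_sigma))
    wy <- diff(stats::pnorm(ey, cy, psf_sigma))
    Wt <- outer(wy, wx)
    num <- sum(Wt * net)
    if (num <= 0) return(NULL)
    cx_new <- sum(Wt * net * matrix(xs, nrow(net), ncol(net), byrow = TRUE)) / num
    cy_new <- sum(Wt * net * matrix(ys, nrow(net), ncol(net))) / num
    moved <- max(abs(cx_new - cx), abs(cy_new - cy))
    cx <- cx_new
    cy <- cy_new
    if (moved < 1e-4 * pixel_size) break
  }
  # photon count from the background-corrected disc sum
  N <- measure_intensity(frame, c(i, j), config)
  if (!is.finite(N) || N <= 0) return(NULL)
  s <- psf_sigma; a <- pixel_size; b <- max(bg_sd, 0)
  prec2 <- (s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2)
  list(x_um = cx, y_um = cy, precision_um = sqrt(prec2), photons = N)
}
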