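# Bleach correction, Chung-Kennedy edge-preserving filtering, single-molecule
# brightness calibration from late-stage photobleaching steps, and conversion
# of initial track intensities to stoichiometries.

#' Temporal bleach correction of a movie
#'
#' Fits the whole-field mean intensity with a mono-exponential plus offset,
#' m(t) = A exp(-k t) + C, and divides each frame by the fitted decay
#' normalized to the first frame. Non-decaying input falls back to the
#' identity correction with a warning.
#'
#' @param movie 3D array (rows x cols x frames).
#' @return List with `movie` (corrected), `params` (A, k, C) and `corrected`
#'   (logical; FALSE when the identity fallback was used).
#' @export
bleach_correct <- function(movie) {
  Tn <- dim(movie)[3]
  if (Tn < 10) stop("bleach_correct needs at least 10 frames", call. = FALSE)
  m <- apply(movie, 3, mean)
  t <- seq_len(Tn) - 1
  C0 <- min(m)
  A0 <- max(m[1] - C0, 1e-6)
  pos <- which(m - C0 > A0 * 1e-3)
  k0 <- if (length(pos) > 2) {
    fit0 <- stats::lm(log(m[pos] - C0 + 1e-12) ~ t[pos])
    max(-stats::coef(fit0)[2], 1e-6)
  } else 1e-3
  fit <- tryCatch(
    stats::nls(m ~ A * exp(-k * t) + C,
               start = list(A = A0, k = k0, C = C0),
               control = stats::nls.control(maxiter = 100, warnOnly = TRUE,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  ok <- !is.null(fit)
  if (ok) {
    p <- stats::coef(fit)
    ok <- is.finite(p["k"]) && p["k"] > 0 && p["A"] > 0
  }
  if (!ok) {
    warning("no photobleaching decay detected; returning identity correction")
    return(list(movie = movie, params = c(A = 0, k = 0, C = mean(m)),
                corrected = FALSE))
  }
  fitted_m <- p["A"] * exp(-p["k"] * t) + p["C"]
  decay <- fitted_m / fitted_m[1]
  corrected <- movie
  for (f in seq_len(Tn)) corrected[, , f] <- movie[, , f] / decay[f]
  list(movie = corrected, params = c(A = unname(p["A"]), k = unname(p["k"]),
                                     C = unname(p["C"])),
       corrected = TRUE)
}

#' Chung-Kennedy edge-preserving filter
#'
#' Each sample is replaced by a weighted combination of a forward (past
#' window) and a backward (future window) running mean, with weights
#' proportional to the inverse of each predictor's recent summed squared
#' prediction error raised to `exponent`. Because the error sums straddle a
#' step asymmetrically, steps are preserved rather than smoothed. Endpoint
#' samples lacking one of the windows are returned unchanged.
#'
#' @param trace Numeric intensity trace.
#' @param window Window length in frames (>= 2), used both for the running
#'   means and the prediction-error sums.
#' @param exponent Positive weighting exponent (default 4; sharper
#'   exponents switch harder between the two predictors near a step).
#' @return Filtered trace of the same length.
#' @export
chung_kennedy <- function(trace, window = 10L, exponent = 4) {
  if (window < 2) stop("parameter error: `window` must be >= 2", call. = FALSE)
  n <- length(trace)
  if (n <= window) stop("trace must be longer than `window`", call. = FALSE)
  W <- as.integer(window)
  eps <- .Machine$double.eps
  cs <- c(0, cumsum(trace))
  # forward predictor: mean of up to W samples strictly before i
  i <- seq_len(n)
  lo_f <- pmax(i - W, 1L); hi_f <- i - 1L
  nf <- pmax(hi_f - lo_f + 1L, 0L)
  mu_f <- ifelse(nf > 0, (cs[pmax(hi_f, 0L) + 1L] - cs[lo_f]) / pmax(nf, 1L), NA)
  # backward predictor: mean of up to W samples strictly after i
  lo_b <- i + 1L; hi_b <- pmin(i + W, n)
  nb <- pmax(hi_b - lo_b + 1L, 0L)
  mu_b <- ifelse(nb > 0, (cs[hi_b + 1L] - cs[pmin(lo_b, n + 1L)]) / pmax(nb, 1L), NA)
  # squared prediction errors where the predictor exists
  err_f <- ifelse(nf > 0, (trace - mu_f)^2, 0)
  err_b <- ifelse(nb > 0, (trace - mu_b)^2, 0)
  csf <- c(0, cumsum(err_f))
  csb <- c(0, cumsum(err_b))
  # forward error sum over the past W points (j in [i-W+1, i]),
  # backward error sum over the future W points (j in [i, i+W-1])
  lo_sf <- pmax(i - W + 1L, 1L)
  s_f <- csf[i + 1L] - csf[lo_sf]
  hi_sb <- pmin(i + W - 1L, n)
  s_b <- csb[hi_sb + 1L] - csb[i]
  w_f <- ifelse(nf > 0, (s_f + eps)^(-exponent), 0)
  w_b <- ifelse(nb > 0, (s_b + eps)^(-exponent), 0)
  out <- trace
  both <- nf > 0 & nb > 0
  out[both] <- (w_f[both] * mu_f[both] + w_b[both] * mu_b[both]) /
    (w_f[both] + w_b[both])
  out
}

# Detect photobleaching steps (decreasing jumps) in a filtered trace.
# Consecutive super-threshold negative differences mark one step edge; the
# step amplitude is the drop in plateau level across the edge, measured as
# the difference of plateau medians taken `gap` samples clear of the edge
# (so residual filter transition does not bias the amplitude). Returns
# positive step sizes.
detect_steps <- function(filtered, raw = filtered, threshold_sd = 3,
                         plateau = 5L, gap = 2L) {
  n <- length(filtered)
  if (n < 3) return(numeric(0))
  noise_sd <- stats::mad(diff(raw)) / sqrt(2)
  # floor guards against numerically flat noiseless traces
  noise_sd <- max(noise_sd, 1e-8 * max(abs(raw), 1))
  d <- diff(filtered)
  hit <- d < -threshold_sd * noise_sd
  if (!any(hit)) return(numeric(0))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  grp <- which(r$values)
  steps <- numeric(0)
  for (gi in seq_along(grp)) {
    g <- grp[gi]
    pre_lo_lim <- if (gi > 1) ends[grp[gi - 1]] + 2L else 1L
    post_hi_lim <- if (gi < length(grp)) starts[grp[gi + 1]] - 1L else n
    pre_hi <- starts[g] - gap
    pre_lo <- max(pre_lo_lim, pre_hi - plateau + 1L)
    post_lo <- ends[g] + 1L + gap
    post_hi <- min(post_hi_lim, post_lo + plateau - 1L)
    if (pre_hi < pre_lo || post_hi < post_lo) {
      # short plateau between close steps: fall back to edge-adjacent windows
      pre_hi <- starts[g]
      pre_lo <- max(pre_lo_lim, pre_hi - plateau + 1L)
      post_lo <- ends[g] + 1L
      post_hi <- min(post_hi_lim, post_lo + plateau - 1L)
    }
    if (pre_hi < pre_lo || post_hi < post_lo) next
    size <- stats::median(filtered[pre_lo:pre_hi]) -
      stats::median(filtered[post_lo:post_hi])
    if (size > threshold_sd * noise_sd) steps <- c(steps, size)
  }
  steps
}
#' Calibrate the characteristic single-molecule brightness
#'
#' Pools downward intensity steps found in the late-stage portion of
#' Chung-Kennedy-filtered track intensity traces and reports the modal step
#' size (Gaussian KDE with Silverman bandwidth, argmax on a 0.1-count grid)
#' as the per-molecule brightness.
#'
#' @param traces List of numeric intensity traces (one per track).
#' @param late_stage_fraction Final fraction of each trace searched for
#'   steps (default 0.5).
#' @param window,exponent Chung-Kennedy filter parameters.
#' @param min_steps Minimum pooled step count for an accepted calibration.
#' @return Object of class `brightness_calibration`: list(b_modal, b_sd,
#'   n_steps_used, steps).
#' @export
calibrate_brightness <- function(traces, late_stage_fraction = 0.5,
                                 window = 10L, exponent = 4,
                                 min_steps = 10L) {
  steps <- numeric(0)
  for (tr in traces) {
    n <- length(tr)
    if (n <= window + 2) next
    filt <- chung_kennedy(tr, window = window, exponent = exponent)
    i0 <- max(1L, floor((1 - late_stage_fraction) * n) + 1L)
    steps <- c(steps, detect_steps(filt[i0:n], raw = tr[i0:n]))
  }
  if (length(steps) < min_steps) {
    stop(structure(class = c("calibration_error", "error", "condition"),
                   list(message = sprintf(
                     "calibration failure: %d steps found, %d required",
                     length(steps), min_steps), call = NULL)))
  }
  if (stats::sd(steps) > 0) {
    bw <- stats::bw.nrd0(steps)
    grid <- seq(0, max(steps) + 3 * bw, by = 0.1)
    dens <- colMeans(stats::dnorm(outer(steps, grid, "-") / bw)) / bw
    b_modal <- grid[which.max(dens)]
  } else {
    b_modal <- steps[1]
  }
  structure(list(b_modal = b_modal, b_sd = stats::sd(steps),
                 n_steps_used = length(steps), steps = steps),
            class = "brightness_calibration")
}

#' Track stoichiometry from initial intensity
#'
#' Fits a least-squares line through the first up-to-`n_initial_frames`
#' intensity samples of a track, evaluates it at the track's first observed
#' frame to undo within-track photobleaching, and divides by the calibrated
#' single-molecule brightness.
#'
#' @param track Data frame with columns `frame` and `intensity` (one track).
#' @param calibration A `brightness_calibration` (or a single positive
#'   number used as b directly).
#' @param config A [stoich_config()].
#' @return One-row data frame: initial_intensity, S, accepted, reason.
#' @export
stoichiometry <- function(track, calibration, config = stoich_config()) {
  b <- if (inherits(calibration, "brightness_calibration"))
    calibration$b_modal else as.numeric(calibration)
  stopifnot_positive(b, "b_modal")
  if (nrow(track) < 2) stop("track needs >= 2 intensity samples", call. = FALSE)
  k <- min(config$n_initial_frames, nrow(track))
  head_tr <- track[seq_len(k), ]
  fit <- stats::lm(intensity ~ frame, data = head_tr)
  initial <- unname(stats::predict(fit, newdata = data.frame(frame = track$frame[1])))
  if (!is.finite(initial) || initial <= 0) {
    return(data.frame(initial_intensity = initial, S = NA_real_,
                      accepted = FALSE, reason = "nonpositive_initial"))
  }
  data.frame(initial_intensity = initial, S = initial / b, accepted = TRUE,
             reason = "")
}

#' Stoichiometries for a table of linked tracks
#'
#' @param tracks Data frame with `track_id`, `frame`, `intensity` (and
#'   optionally `nucleus_id`).
#' @inheritParams stoichiometry
#' @return Data frame with one row per accepted track: track_id, nucleus_id,
#'   initial_intensity, S.
#' @export
stoichiometry_table <- function(tracks, calibration, config = stoich_config()) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(NULL)
    s <- stoichiometry(tr, calibration, config)
    if (!s$accepted) return(NULL)
    data.frame(track_id = tr$track_id[1],
               nucleus_id = if ("nucleus_id" %in% names(tr))
                 tr$nucleus_id[1] else NA_integer_,
               initial_intensity = s$initial_intensity, S = s$S)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), nucleus_id = integer(0),
                      initial_intensity = numeric(0), S = numeric(0))
  }
  rownames(out) <- NULL
  out
}
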