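# Mean-square displacement and 2D random-walk diffusion estimation.

#' Time-averaged mean-square displacement of a track
#'
#' msd(tau) is the mean over all ordered frame pairs separated by tau of the
#' squared 2D displacement. Frame gaps are respected: only pairs actually
#' separated by the lag contribute.
#'
#' @param track Data frame with columns `frame`, `x_um`, `y_um`.
#' @param frame_interval Frame interval in seconds.
#' @param max_lag Maximum lag in frames (default all available).
#' @return Object of class `msd_curve`: data frame with columns `lag_s`,
#'   `msd_um2`, `n_pairs`.
#' @export
msd <- function(track, frame_interval = 0.0125, max_lag = NULL) {
  track <- track[order(track$frame), ]
  f <- track$frame
  span <- max(f) - min(f)
  if (is.null(max_lag)) max_lag <- span
  lags <- seq_len(min(max_lag, span))
  vals <- numeric(length(lags))
  cnt <- integer(length(lags))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    j <- match(f + tau, f)
    ok <- !is.na(j)
    cnt[li] <- sum(ok)
    if (cnt[li] > 0) {
      vals[li] <- mean((track$x_um[which(ok)] - track$x_um[j[ok]])^2 +
                         (track$y_um[which(ok)] - track$y_um[j[ok]])^2)
    } else vals[li] <- NA_real_
  }
  keep <- cnt > 0
  structure(data.frame(lag_s = lags[keep] * frame_interval,
                       msd_um2 = vals[keep], n_pairs = cnt[keep]),
            class = c("msd_curve", "data.frame"))
}

#' Fit a 2D diffusion coefficient to an MSD curve
#'
#' Weighted least-squares line msd = 4 D tau + c over the first `n_lags`
#' lags (weights = pair counts). The intercept c absorbs the localization
#' error (c ~ 4 sigma_loc^2). Negative estimates are retained but flagged.
#'
#' @param curve An `msd_curve`.
#' @param n_lags Number of initial lags to fit (default 4).
#' @return Object of class `diffusion_estimate`: list(D, intercept,
#'   n_lags_used, negative).
#' @export
fit_diffusion <- function(curve, n_lags = 4L) {
  use <- curve[seq_len(min(n_lags, nrow(curve))), ]
  if (nrow(use) < 2) stop("estimate failure: fewer than 2 usable lags",
                          call. = FALSE)
  fit <- stats::lm(msd_um2 ~ lag_s, data = use, weights = use$n_pairs)
  slope <- unname(stats::coef(fit)[2])
  D <- slope / 4
  structure(list(D = D, intercept = unname(stats::coef(fit)[1]),
                 n_lags_used = nrow(use), negative = D < 0),
            class = "diffusion_estimate")
}

#' Per-track diffusion estimates for a table of linked tracks
#'
#' @param tracks Data frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @inheritParams msd
#' @inheritParams fit_diffusion
#' @return Data frame: track_id, D, intercept, n_lags_used, negative.
#' @export
diffusion_table <- function(tracks, frame_interval = 0.0125, n_lags = 4L) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    est <- tryCatch(fit_diffusion(msd(tr, frame_interval), n_lags),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(track_id = tr$track_id[1], D = est$D,
               intercept = est$intercept, n_lags_used = est$n_lags_used,
               negative = est$negative)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(track_id = integer(0), D = numeric(0),
                                      intercept = numeric(0),
                                      n_lags_used = integer(0),
                                      negative = logical(0))
  rownames(out) <- NULL
  out
}

#' Mobility grouped by stoichiometry threshold
#'
#' Splits tracks at a stoichiometry threshold (default 10 molecules) and
#' reports mean, s.d. and n of the diffusion coefficient in each group.
#'
#' @param table Data frame with columns `S` and `D`.
#' @param threshold Stoichiometry split point (group "low" is S < threshold,
#'   "high" is S >= threshold).
#' @return Data frame with rows for the non-empty groups: group, mean_D,
#'   sd_D, n.
#' @export
mobility_by_stoichiometry <- function(table, threshold = 10) {
  stopifnot(nrow(table) > 0)
  grp <- ifelse(table$S < threshold, "low", "high")
  out <- lapply(c("low", "high"), function(g) {
    d <- table$D[grp == g]
    if (length(d) == 0) return(NULL)
    data.frame(group = g, mean_D = mean(d), sd_D = stats::sd(d),
               n = length(d))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
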