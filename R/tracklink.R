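# Frame-to-frame linking of foci into tracks by optimal (min squared
# displacement) assignment, random-overlap estimation and nucleus masking.

# Jonker-Volgenant style shortest-augmenting-path solver for the linear
# assignment problem. `cost` is an n x m matrix with n <= m; returns for
# each row the assigned column index. Forbidden links should be encoded as
# large finite costs.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  INF <- .Machine$double.xmax / 4
  # columns indexed 1..m+1 with column 1 a virtual slot (e-maxx layout)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)     # p[j] = row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      free_j <- which(!used)
      cur <- cost[i0, free_j - 1L] - u[i0 + 1L] - v[free_j]
      upd <- cur < minv[free_j]
      minv[free_j[upd]] <- cur[upd]
      way[free_j[upd]] <- j0
      jmin <- free_j[which.min(minv[free_j])]
      delta <- minv[jmin]
      j1 <- jmin
      u[p[used] + 1L] <- u[p[used] + 1L] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(m + 1L)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Link per-frame foci into tracks
#'
#' Foci in consecutive frames are linked by an optimal assignment minimizing
#' total squared displacement; links longer than the displacement budget are
#' forbidden, unmatched foci start new tracks, and a track may bridge up to
#' `max_gap` missing frames with its displacement budget scaled by
#' sqrt(gap + 1). Foci within each frame are processed in a canonical
#' (x, then y) order, so the result does not depend on input ordering.
#'
#' @param foci Data frame of detections with at least columns `frame`,
#'   `x_um`, `y_um` (any further columns are carried through).
#' @param config A [linking_config()].
#' @return Data frame of the input foci that belong to accepted tracks, with
#'   a `track_id` column, ordered by track then frame. Tracks shorter than
#'   `min_track_length` are dropped.
#' @export
link_tracks <- function(foci, config = linking_config()) {
  if (is.null(foci) || nrow(foci) == 0) {
    return(cbind(foci[0, , drop = FALSE], track_id = integer(0)))
  }
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(foci)))
  foci <- foci[order(foci$frame, foci$x_um, foci$y_um), , drop = FALSE]
  rownames(foci) <- NULL
  BIG <- 1e12
  budget1 <- config$max_displacement
  track_of <- rep(NA_integer_, nrow(foci))
  # per-track state
  last_row <- integer(0)   # focus row index of the track head
  last_frame <- integer(0)
  n_tracks <- 0L
  frames <- sort(unique(foci$frame))
  for (f in frames) {
    idx_f <- which(foci$frame == f)
    active <- which(last_frame < f & (f - last_frame) <= config$max_gap + 1L)
    if (length(active) == 0L) {
      for (r in idx_f) {
        n_tracks <- n_tracks + 1L
        track_of[r] <- n_tracks
        last_row[n_tracks] <- r
        last_frame[n_tracks] <- f
      }
      next
    }
    nt <- length(active); nf <- length(idx_f)
    dgap <- f - last_frame[active]
    dx <- outer(foci$x_um[last_row[active]], foci$x_um[idx_f], "-")
    dy <- outer(foci$y_um[last_row[active]], foci$y_um[idx_f], "-")
    d2 <- dx^2 + dy^2
    feas <- d2 <= (budget1 * sqrt(dgap))^2
    link_cost <- ifelse(feas, d2, BIG)
    unmatch <- (budget1 * sqrt(config$max_gap + 1))^2 * (1 + 1e-9) + 1e-12
    cost <- matrix(BIG, nt + nf, nf + nt)
    cost[seq_len(nt), seq_len(nf)] <- link_cost
    cost[cbind(seq_len(nt), nf + seq_len(nt))] <- unmatch       # track unmatched
    cost[cbind(nt + seq_len(nf), seq_len(nf))] <- unmatch       # focus -> new track
    cost[nt + seq_len(nf), nf + seq_len(nt)] <- 0               # dummy-dummy
    assign <- solve_assignment(cost)
    for (t in seq_len(nt)) {
      j <- assign[t]
      if (j <= nf && link_cost[t, j] < BIG) {
        r <- idx_f[j]
        tr <- track_of[last_row[active[t]]]
        track_of[r] <- tr
        last_row[tr] <- r
        last_frame[tr] <- f
      }
    }
    for (j in which(is.na(track_of[idx_f]))) {
      r <- idx_f[j]
      n_tracks <- n_tracks + 1L
      track_of[r] <- n_tracks
      last_row[n_tracks] <- r
      last_frame[n_tracks] <- f
    }
  }
  foci$track_id <- track_of
  keep <- table(track_of)
  keep_ids <- as.integer(names(keep)[keep >= config$min_track_length])
  out <- foci[foci$track_id %in% keep_ids, , drop = FALSE]
  # renumber tracks consecutively in order of first appearance
  out$track_id <- as.integer(factor(out$track_id, levels = unique(out$track_id)))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random overlap probability of foci
#'
#' Fraction of foci whose nearest same-frame neighbour lies within
#' `overlap_radius` (closed boundary: a pair exactly at the radius counts as
#' overlapping). Foci that are alone in their frame count as non-overlapping.
#'
#' @param foci Data frame with columns `frame`, `x_um`, `y_um`.
#' @param overlap_radius Radius in um.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_probability <- function(foci, overlap_radius) {
  stopifnot(nrow(foci) >= 1)
  n_overlap <- 0L
  for (f in unique(foci$frame)) {
    sub <- foci[foci$frame == f, c("x_um", "y_um"), drop = FALSE]
    if (nrow(sub) < 2) next
    dm <- as.matrix(stats::dist(sub))
    diag(dm) <- Inf
    n_overlap <- n_overlap + sum(apply(dm, 1, min) <= overlap_radius)
  }
  n_overlap / nrow(foci)
}

#' Restrict foci or tracks to nucleus masks
#'
#' Keeps only items whose position falls inside the (manually segmented)
#' nucleus mask and attaches the id of the mask's connected component as
#' `nucleus_id`.
#'
#' @param foci Data frame with `x_um`, `y_um` columns (foci or linked
#'   tracks).
#' @param mask Logical or 0/1 matrix on the frame pixel grid
#'   (rows = y, cols = x).
#' @param pixel_size Pixel size in um.
#' @return The filtered data frame with a `nucleus_id` column.
#' @export
apply_nucleus_mask <- function(foci, mask, pixel_size = 0.053) {
  mask <- mask > 0
  if (!any(mask)) {
    warning("nucleus mask is empty; no foci retained")
    return(cbind(foci[0, , drop = FALSE], nucleus_id = integer(0)))
  }
  labels <- EBImage::bwlabel(mask)
  i <- pmin(pmax(floor(foci$y_um / pixel_size) + 1L, 1L), nrow(mask))
  j <- pmin(pmax(floor(foci$x_um / pixel_size) + 1L, 1L), ncol(mask))
  lab <- labels[cbind(i, j)]
  out <- foci[lab > 0, , drop = FALSE]
  out$nucleus_id <- as.integer(lab[lab > 0])
  rownames(out) <- NULL
  out
}
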