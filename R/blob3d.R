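# Seeded 3D blob segmentation (scale-matched LoG seeding + descending-order
# watershed flood with saddle-depth basin merging), object metrics with
# mesh-based sphericity, channel alignment and intersection colocalization.
#
# Stacks are arrays indexed [x, y, z] with a physical voxel size (um) per
# axis; positions in um map to voxel centres at (index - 0.5) * voxel_size.

# Scale-normalized (negated) Laplacian of the Gaussian-smoothed stack, so
# that blob interiors are positive. Finite differences use the physical
# voxel spacing; the response is multiplied by sigma^2 (the blob scale).
blob_response <- function(stack, voxel_size, sigma_um) {
  sig_vox <- sigma_um / voxel_size
  d <- dim(stack)
  kz <- ceiling(4 * sig_vox[3])
  if (d[3] < max(3, kz)) {
    stop(sprintf(
      "stack too thin along z for the blob scale (need >= %d slices, have %d)",
      max(3, kz), d[3]), call. = FALSE)
  }
  sm <- gauss_smooth3(stack, sig_vox)
  lap <- array(0, d)
  for (ax in 1:3) {
    h <- voxel_size[ax]
    lo <- sm; hi <- sm
    idx <- slice.index(sm, ax)
    # second difference with replicated edges
    shift_up <- function(a, ax) {
      d <- dim(a)
      ii <- pmin(slice.index(a, ax) + 1L, d[ax])
      take_along(a, ii, ax)
    }
    shift_dn <- function(a, ax) {
      ii <- pmax(slice.index(a, ax) - 1L, 1L)
      take_along(a, ii, ax)
    }
    lap <- lap + (shift_up(sm, ax) - 2 * sm + shift_dn(sm, ax)) / h^2
  }
  list(response = -lap * sigma_um^2, smoothed = sm)
}

# Index an array along one axis with a per-position index array of the same
# shape (gather).
take_along <- function(a, idx, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  ip <- aperm(idx, perm)
  dm <- dim(ap)
  dim(ap) <- c(dm[1], prod(dm[-1]))
  dim(ip) <- dim(ap)
  out <- ap[cbind(as.vector(ip), rep(seq_len(ncol(ap)), each = dm[1]))]
  dim(out) <- dm
  aperm(out, order(perm))
}

#' Seeded 3D blob segmentation
#'
#' Seeds are 26-connected local maxima of the scale-matched, normalized
#' Laplacian-of-Gaussian response (per-axis sigma = diameter / (2 sqrt(3)) /
#' voxel size) whose normalized response reaches the probability threshold
#' (percent of the maximum response). Watershed basins are grown from the
#' seeds over the smoothed intensity in descending order; two basins merge
#' when the saddle depth between them is at most
#' (1 - split_sensitivity/100) times the lower basin height (both measured
#' above the stack floor), so 0% merges all touching basins and 100% never
#' merges. Labels are restricted to the positive-response (blob interior)
#' support.
#'
#' @param stack 3D array (x, y, z) of intensities, single channel.
#' @param voxel_size Numeric c(x, y, z) voxel edges in um.
#' @param params A [blob_params()].
#' @return Integer label array of the same dimension (0 = background), with
#'   attribute `n_objects`.
#' @export
blob_segment <- function(stack, voxel_size, params = blob_params()) {
  stopifnot(length(dim(stack)) == 3, length(voxel_size) == 3)
  sigma_um <- params$diameter / (2 * sqrt(3))
  br <- blob_response(stack, voxel_size, sigma_um)
  resp <- br$response
  sm <- br$smoothed
  d <- dim(stack)
  mx <- max(resp)
  labels <- array(0L, d)
  # a flat stack has no blob response (up to smoothing round-off)
  rng <- diff(range(stack))
  if (mx <= 0 || rng == 0 || mx < 1e-8 * rng) {
    attr(labels, "n_objects") <- 0L
    return(labels)
  }
  resp_norm <- 100 * resp / mx
  seeds <- local_maxima3(resp, mask = resp_norm >= params$probability_threshold)
  if (nrow(seeds) == 0) { attr(labels, "n_objects") <- 0L; return(labels) }
  # deterministic seed order: by decreasing response, then linear index
  lin <- (seeds[, 3] - 1L) * d[1] * d[2] + (seeds[, 2] - 1L) * d[1] + seeds[, 1]
  o <- order(-resp[cbind(seeds[, 1], seeds[, 2], seeds[, 3])], lin)
  seeds <- seeds[o, , drop = FALSE]
  lin <- lin[o]
  ns <- nrow(seeds)
  lab <- integer(prod(d))
  lab[lin] <- seq_len(ns)
  smv <- as.vector(sm)
  floor_v <- min(smv)
  # descending flood: assign each voxel to the labelled 6-neighbour with the
  # highest smoothed intensity; record the first (= highest) saddle value
  # for each pair of basins that meet
  ord <- order(-smv)
  strides <- c(1L, d[1], d[1] * d[2])
  saddle <- list()
  seed_height <- smv[lin]
  for (v in ord) {
    if (lab[v] > 0L) {
      # seeds are pre-labelled; still check for saddle contacts below
    }
    i <- ((v - 1L) %% d[1]) + 1L
    j <- (((v - 1L) %/% d[1]) %% d[2]) + 1L
    k <- ((v - 1L) %/% strides[3]) + 1L
    nb <- integer(0)
    if (i > 1L) nb <- c(nb, v - 1L)
    if (i < d[1]) nb <- c(nb, v + 1L)
    if (j > 1L) nb <- c(nb, v - d[1])
    if (j < d[2]) nb <- c(nb, v + d[1])
    if (k > 1L) nb <- c(nb, v - strides[3])
    if (k < d[3]) nb <- c(nb, v + strides[3])
    nl <- lab[nb]
    nl <- unique(nl[nl > 0L])
    if (lab[v] == 0L) {
      if (length(nl) == 0L) next
      # attach to the neighbouring basin whose voxel is highest
      if (length(nl) == 1L) lab[v] <- nl
      else {
        hts <- vapply(nl, function(L) max(smv[nb[lab[nb] == L]]), numeric(1))
        lab[v] <- nl[which.max(hts)]
      }
    }
    others <- setdiff(nl, lab[v])
    for (L2 in others) {
      key <- paste(min(lab[v], L2), max(lab[v], L2))
      if (is.null(saddle[[key]])) saddle[[key]] <- smv[v]
    }
  }
  # merge basins by saddle depth (union-find)
  parent <- seq_len(ns)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  thr_frac <- 1 - params$split_sensitivity / 100
  if (length(saddle)) {
    keys <- names(saddle)
    svals <- unlist(saddle)
    o2 <- order(-svals)
    for (q in o2) {
      ab <- as.integer(strsplit(keys[q], " ")[[1]])
      ra <- find(ab[1]); rb <- find(ab[2])
      if (ra == rb) next
      ha <- max(seed_height[ra], seed_height[ab[1]])
      hb <- max(seed_height[rb], seed_height[ab[2]])
      depth <- min(ha, hb) - svals[q]
      if (depth <= thr_frac * (min(ha, hb) - floor_v)) {
        # merge into the taller basin's root
        if (seed_height[ra] >= seed_height[rb]) parent[rb] <- ra
        else parent[ra] <- rb
      }
    }
  }
  root <- vapply(seq_len(ns), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  # restrict to blob-interior support and relabel consecutively
  support <- as.vector(resp) > 0
  lab[!support] <- 0L
  ids <- unique(lab[lab > 0L])
  ids <- ids[order(match(ids, lab))]  # order of first voxel occurrence
  relab <- integer(ns)
  relab[ids] <- seq_along(ids)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  labels <- array(lab, d)
  attr(labels, "n_objects") <- length(ids)
  labels
}

# Marching-tetrahedra surface area of an isosurface of the lightly smoothed
# binary mask, in physical units. The mask is zero-padded so the surface
# closes and smoothed with sigma = 0.55 voxels per axis to undo the
# digitization staircase. The iso level is half the maximum smoothed value
# over the original mask voxels, so structures thinner than the smoothing
# kernel still produce a closed surface instead of vanishing.
mesh_surface_area <- function(mask, voxel_size, smooth_sigma = 0.55) {
  d <- dim(mask)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2L), 3:(d[2] + 2L), 3:(d[3] + 2L)] <- as.numeric(mask)
  f <- gauss_smooth3(pad, rep(smooth_sigma, 3))
  dp <- dim(f)
  interior_max <- max(f[3:(d[1] + 2L), 3:(d[2] + 2L), 3:(d[3] + 2L)][mask > 0])
  iso <- 0.5 * max(interior_max, .Machine$double.eps)
  # cube corner offsets (x, y, z) in the standard bit order
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  # 6 tetrahedra sharing the main diagonal c1-c7 (1-based corners 1 and 7)
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  # find cells whose corner values straddle the iso level
  base <- f[1:(dp[1] - 1), 1:(dp[2] - 1), 1:(dp[3] - 1)]
  mn <- base; mxv <- base
  for (ci in 2:8) {
    o <- corners[ci, ]
    cc <- f[(1 + o[1]):(dp[1] - 1 + o[1]), (1 + o[2]):(dp[2] - 1 + o[2]),
            (1 + o[3]):(dp[3] - 1 + o[3])]
    mn <- pmin(mn, cc)
    mxv <- pmax(mxv, cc)
  }
  cells <- which(mn < iso & mxv >= iso, arr.ind = TRUE)
  if (nrow(cells) == 0) return(0)
  area <- 0
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(cr^2))
  }
  interp <- function(pa, va, pb, vb) {
    t <- (iso - va) / (vb - va)
    pa + t * (pb - pa)
  }
  for (ci in seq_len(nrow(cells))) {
    cx <- cells[ci, 1]; cy <- cells[ci, 2]; cz <- cells[ci, 3]
    vals <- numeric(8)
    pts <- matrix(0, 8, 3)
    for (co in 1:8) {
      o <- corners[co, ]
      vals[co] <- f[cx + o[1], cy + o[2], cz + o[3]]
      pts[co, ] <- (c(cx, cy, cz) + o) * voxel_size
    }
    for (tt in 1:6) {
      vi <- tets[tt, ]
      tv <- vals[vi]
      tp <- pts[vi, , drop = FALSE]
      above <- tv >= iso
      na <- sum(above)
      if (na == 0 || na == 4) next
      if (na == 1 || na == 3) {
        lone <- if (na == 1) which(above) else which(!above)
        rest <- setdiff(1:4, lone)
        e <- lapply(rest, function(r)
          interp(tp[lone, ], tv[lone], tp[r, ], tv[r]))
        area <- area + tri_area(e[[1]], e[[2]], e[[3]])
      } else {
        aa <- which(above); bb <- which(!above)
        q1 <- interp(tp[aa[1], ], tv[aa[1]], tp[bb[1], ], tv[bb[1]])
        q2 <- interp(tp[aa[1], ], tv[aa[1]], tp[bb[2], ], tv[bb[2]])
        q3 <- interp(tp[aa[2], ], tv[aa[2]], tp[bb[2], ], tv[bb[2]])
        q4 <- interp(tp[aa[2], ], tv[aa[2]], tp[bb[1], ], tv[bb[1]])
        area <- area + tri_area(q1, q2, q3) + tri_area(q1, q3, q4)
      }
    }
  }
  area
}

#' Per-object metrics of a labelled volume
#'
#' Volume (voxel count x voxel volume), mesh surface area (marching
#' tetrahedra on the 0.5-isosurface of the lightly smoothed object mask),
#' Wadell sphericity pi^(1/3) (6V)^(2/3) / A, mean and total intensity, and
#' centroid in um.
#'
#' @param labels Integer label array (x, y, z).
#' @param stack Intensity array of the same shape.
#' @param voxel_size Numeric c(x, y, z) in um.
#' @return Data frame: label, n_voxels, volume_um3, area_um2, sphericity,
#'   mean_intensity, total_intensity, x_um, y_um, z_um.
#' @export
object_metrics <- function(labels, stack, voxel_size) {
  if (!all(dim(labels) == dim(stack))) {
    stop("labels and stack shapes differ", call. = FALSE)
  }
  vox_vol <- prod(voxel_size)
  ids <- sort(unique(labels[labels > 0]))
  out <- lapply(ids, function(L) {
    idx <- which(labels == L, arr.ind = TRUE)
    nv <- nrow(idx)
    vol <- nv * vox_vol
    inten <- stack[labels == L]
    # crop a padded bounding box for the surface mesh
    lo <- pmax(apply(idx, 2, min) - 3L, 1L)
    hi <- pmin(apply(idx, 2, max) + 3L, dim(labels))
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == L
    area <- mesh_surface_area(sub, voxel_size)
    sph <- if (area > 0) pi^(1 / 3) * (6 * vol)^(2 / 3) / area else NA_real_
    data.frame(label = L, n_voxels = nv, volume_um3 = vol, area_um2 = area,
               sphericity = sph, mean_intensity = mean(inten),
               total_intensity = sum(inten),
               x_um = mean((idx[, 1] - 0.5) * voxel_size[1]),
               y_um = mean((idx[, 2] - 0.5) * voxel_size[2]),
               z_um = mean((idx[, 3] - 0.5) * voxel_size[3]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(label = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), area_um2 = numeric(0),
                      sphericity = numeric(0), mean_intensity = numeric(0),
                      total_intensity = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Filter segmented objects by volume, sphericity and a nucleus mask
#'
#' Removes objects below the minimum volume or minimum mesh sphericity, and
#' optionally objects whose centroid lies outside a nucleus mask. Increasing
#' either threshold can only decrease the number of surviving objects.
#'
#' @param labels Integer label array (x, y, z).
#' @param voxel_size Numeric c(x, y, z) in um.
#' @param params A [filter_params()].
#' @param nucleus_mask Optional logical array of the same shape.
#' @return Relabelled integer array with attribute `n_objects` and
#'   attribute `removed` (labels that were filtered out).
#' @export
filter_objects <- function(labels, voxel_size, params = filter_params(),
                           nucleus_mask = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) { attr(labels, "n_objects") <- 0L; return(labels) }
  m <- object_metrics(labels, array(0, dim(labels)), voxel_size)
  keep <- m$volume_um3 >= params$min_volume &
    !is.na(m$sphericity) & m$sphericity >= params$min_sphericity
  if (!is.null(nucleus_mask)) {
    ci <- pmin(pmax(ceiling(m$x_um / voxel_size[1]), 1L), dim(labels)[1])
    cj <- pmin(pmax(ceiling(m$y_um / voxel_size[2]), 1L), dim(labels)[2])
    ck <- pmin(pmax(ceiling(m$z_um / voxel_size[3]), 1L), dim(labels)[3])
    keep <- keep & nucleus_mask[cbind(ci, cj, ck)] > 0
  }
  kept_ids <- m$label[keep]
  out <- array(0L, dim(labels))
  for (r in seq_along(kept_ids)) out[labels == kept_ids[r]] <- r
  attr(out, "n_objects") <- length(kept_ids)
  attr(out, "removed") <- m$label[!keep]
  out
}

#' Estimate and apply the chromatic shift between two channels
#'
#' The 3D shift of channel 2 relative to channel 1 is the peak of their
#' circular cross-correlation (via FFT), refined per axis by three-point
#' parabolic interpolation; channel 2 is re-sampled by trilinear
#' interpolation. When the normalized correlation peak falls below the
#' confidence floor, a zero shift is returned with a warning.
#'
#' @param ch1,ch2 3D arrays of the same shape (e.g. bead stacks).
#' @param voxel_size Numeric c(x, y, z) in um.
#' @param min_correlation Confidence floor on the normalized peak (0-1).
#' @return List with `shift_vox` (c(x, y, z), the displacement of ch2
#'   relative to ch1), `shift_um`, `correlation`, and `apply(stack)` -- a
#'   function resampling a stack to undo the shift.
#' @export
align_channels <- function(ch1, ch2, voxel_size = c(1, 1, 1),
                           min_correlation = 0.1) {
  stopifnot(all(dim(ch1) == dim(ch2)))
  d <- dim(ch1)
  a <- ch1 - mean(ch1)
  b <- ch2 - mean(ch2)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    length(a)
  ccn <- cc / max(sqrt(sum(a^2) * sum(b^2)), .Machine$double.eps)
  pk <- which(ccn == max(ccn), arr.ind = TRUE)[1, ]
  if (max(ccn) < min_correlation) {
    warning("correlation peak below confidence floor; assuming zero shift")
    shift <- c(0, 0, 0)
  } else {
    shift <- numeric(3)
    for (ax in 1:3) {
      idx <- pk
      get3 <- function(o) {
        idx[ax] <- ((pk[ax] - 1 + o) %% d[ax]) + 1
        ccn[matrix(idx, 1)]
      }
      y0 <- get3(-1); y1 <- get3(0); y2 <- get3(1)
      denom2 <- y0 - 2 * y1 + y2
      off <- if (denom2 < 0) 0.5 * (y0 - y2) / denom2 else 0
      s <- (pk[ax] - 1) + off
      if (s > d[ax] / 2) s <- s - d[ax]
      # cross-correlation peak at lag s means ch2 = ch1 shifted by -s
      shift[ax] <- -s
    }
  }
  list(shift_vox = shift, shift_um = shift * voxel_size,
       correlation = max(ccn),
       apply = function(stack) shift_array3(stack, -shift))
}

#' Intersection colocalization of two labelled volumes
#'
#' The voxel-wise AND of the two label volumes defines the intersection
#' objects (6-connected components). An object in one channel is
#' co-localized iff it shares at least one voxel with any object of the
#' other channel.
#'
#' @param labels_a,labels_b Integer label arrays of the same shape (aligned).
#' @return List with `intersection` (label array of the AND region),
#'   `a` and `b` (data frames: label, n_voxels, colocalized), and
#'   `fraction_a_colocalized` / `fraction_b_colocalized`.
#' @export
colocalize <- function(labels_a, labels_b) {
  if (!all(dim(labels_a) == dim(labels_b))) {
    stop("label volumes have different shapes", call. = FALSE)
  }
  inter_mask <- labels_a > 0 & labels_b > 0
  inter <- label_components3(inter_mask)
  flag_tab <- function(lab, other) {
    ids <- sort(unique(lab[lab > 0]))
    if (!length(ids)) {
      return(data.frame(label = integer(0), n_voxels = integer(0),
                        colocalized = logical(0)))
    }
    data.frame(label = ids,
               n_voxels = vapply(ids, function(L) sum(lab == L), integer(1)),
               colocalized = vapply(ids, function(L)
                 any(other[lab == L] > 0), logical(1)))
  }
  ta <- flag_tab(labels_a, labels_b)
  tb <- flag_tab(labels_b, labels_a)
  list(intersection = inter, a = ta, b = tb,
       fraction_a_colocalized = if (nrow(ta)) mean(ta$colocalized) else NA_real_,
       fraction_b_colocalized = if (nrow(tb)) mean(tb$colocalized) else NA_real_)
}
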