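# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve along the first dimension of a matrix-shaped array with
# replicate-free edge handling: truncated kernel rows are renormalized so a
# constant input stays exactly constant.
conv_axis1 <- function(m, k) {
  n <- nrow(m)
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(m)
  # band matrix T[i, j] = k[j - i + r + 1] for |i - j| <= r, rows renormalized
  Tm <- matrix(0, n, n)
  for (d in -r:r) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) Tm[cbind(idx, idx + d)] <- k[d + r + 1L]
    else Tm[cbind(idx - d, idx)] <- k[d + r + 1L]
  }
  Tm <- Tm / rowSums(Tm)
  Tm %*% m
}

# Separable Gaussian smoothing of a 2D matrix (sigma in pixels, scalar or
# length-2 per axis: rows, cols).
gauss_smooth2 <- function(img, sigma, truncate = 4) {
  sigma <- rep(sigma, length.out = 2)
  out <- img
  if (sigma[1] > 0) out <- conv_axis1(out, gauss_kernel(sigma[1], truncate))
  if (sigma[2] > 0) out <- t(conv_axis1(t(out), gauss_kernel(sigma[2], truncate)))
  out
}

# Separable Gaussian smoothing of a 3D array; sigma length-3 in voxels.
gauss_smooth3 <- function(a, sigma, truncate = 4) {
  d <- dim(a)
  stopifnot(length(d) == 3)
  sigma <- rep(sigma, length.out = 3)
  out <- a
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gauss_kernel(sigma[ax], truncate)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(out, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], prod(dm[-1]))
    m <- conv_axis1(m, k)
    dim(m) <- dm
    out <- aperm(m, order(perm))
  }
  out
}

# Strict 26-connected local maxima of a 3D array; returns integer matrix of
# voxel indices (i, j, k). A voxel must exceed every in-bounds neighbour.
local_maxima3 <- function(a, mask = NULL) {
  d <- dim(a)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  ok <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- pad[(2:(d[1] + 1L)) + di, (2:(d[2] + 1L)) + dj, (3:(d[3] + 2L)) + dk - 1L,
              drop = FALSE]
    dim(nb) <- d
    ok <- ok & (a > nb)
  }
  if (!is.null(mask)) ok <- ok & mask
  which(ok, arr.ind = TRUE)
}

# Strict 8-connected local maxima of a matrix, excluding a border margin.
local_maxima2 <- function(m, margin = 1L) {
  d <- dim(m)
  pad <- matrix(-Inf, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  ok <- matrix(TRUE, d[1], d[2])
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (m > pad[(2:(d[1] + 1L)) + di, (2:(d[2] + 1L)) + dj])
  }
  if (margin > 0L) {
    ok[seq_len(min(margin, d[1])), ] <- FALSE
    ok[seq(max(1L, d[1] - margin + 1L), d[1]), ] <- FALSE
    ok[, seq_len(min(margin, d[2]))] <- FALSE
    ok[, seq(max(1L, d[2] - margin + 1L), d[2])] <- FALSE
  }
  which(ok, arr.ind = TRUE)
}

# Union-find with path compression.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# 6-connected components of a 3D logical array; returns integer label array.
label_components3 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(lab)
  strides <- c(1L, d[1], d[1] * d[2])
  pos_of <- function(idx) {
    k <- (idx - 1L) %/% strides[3]
    r <- (idx - 1L) %% strides[3]
    j <- r %/% strides[1] %/% d[1] * 0L  # placeholder, computed below
    i <- r %% d[1]
    j <- r %/% d[1]
    cbind(i + 1L, j + 1L, k + 1L)
  }
  visited <- array(FALSE, d)
  for (s in idx_all) {
    if (visited[s]) next
    nxt <- nxt + 1L
    frontier <- s
    visited[s] <- TRUE
    while (length(frontier)) {
      lab[frontier] <- nxt
      p <- pos_of(frontier)
      nbrs <- integer(0)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        q <- p
        q[, ax] <- q[, ax] + dd
        keep <- q[, ax] >= 1L & q[, ax] <= d[ax]
        if (!any(keep)) next
        qi <- q[keep, , drop = FALSE]
        nbrs <- c(nbrs, (qi[, 3] - 1L) * strides[3] + (qi[, 2] - 1L) * d[1] + qi[, 1])
      }
      nbrs <- unique(nbrs[mask[nbrs] & !visited[nbrs]])
      visited[nbrs] <- TRUE
      frontier <- nbrs
    }
  }
  lab
}

# Shift a 3D array by a fractional voxel offset (trilinear interpolation,
# edge values extended). shift = c(dz, dy, dx) ... in array index units
# (dim1, dim2, dim3). Positive shift moves content toward higher indices.
shift_array3 <- function(a, shift) {
  d <- dim(a)
  out <- array(0, d)
  # sample coordinates in the source for each target voxel
  g1 <- seq_len(d[1]) - shift[1]
  g2 <- seq_len(d[2]) - shift[2]
  g3 <- seq_len(d[3]) - shift[3]
  cl <- function(x, n) pmin(pmax(x, 1), n)
  f1 <- floor(g1); f2 <- floor(g2); f3 <- floor(g3)
  w1 <- g1 - f1; w2 <- g2 - f2; w3 <- g3 - f3
  i10 <- cl(f1, d[1]); i11 <- cl(f1 + 1, d[1])
  i20 <- cl(f2, d[2]); i21 <- cl(f2 + 1, d[2])
  i30 <- cl(f3, d[3]); i31 <- cl(f3 + 1, d[3])
  for (k in seq_len(d[3])) {
    a0 <- a[, , i30[k]]
    a1 <- a[, , i31[k]]
    sl <- a0 * (1 - w3[k]) + a1 * w3[k]
    # bilinear in-plane
    m00 <- sl[i10, i20, drop = FALSE]
    m10 <- sl[i11, i20, drop = FALSE]
    m01 <- sl[i10, i21, drop = FALSE]
    m11 <- sl[i11, i21, drop = FALSE]
    W1 <- matrix(w1, d[1], d[2])
    W2 <- matrix(w2, d[1], d[2], byrow = TRUE)
    out[, , k] <- m00 * (1 - W1) * (1 - W2) + m10 * W1 * (1 - W2) +
      m01 * (1 - W1) * W2 + m11 * W1 * W2
  }
  out
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("parameter error: `%s` must be positive and finite", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("parameter error: `%s` must be non-negative and finite", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
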