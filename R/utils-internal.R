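# Internal raster helpers: exact windowed statistics, separable Gaussian
# smoothing with truncated-window normalization, and 8-connected component
# labeling.  Windowed sums are accumulated by integer shifts over the offset
# set (no FFT), so results are exact sums of the in-bounds window pixels.

# Offsets (dy, dx) of the circular window of the given pixel radius:
# dy^2 + dx^2 <= r^2.
disc_offsets <- function(radius_px) {
  r <- as.integer(radius_px)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius_px^2, , drop = FALSE]
}

pad_matrix <- function(m, r, value = 0) {
  out <- matrix(value, nrow(m) + 2 * r, ncol(m) + 2 * r)
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))] <- m
  out
}

# Mean, population SD and in-bounds count over the circular window at each
# pixel; border windows are truncated (statistics over in-bounds pixels only).
local_window_stats <- function(values, radius_px) {
  r <- as.integer(ceiling(radius_px))
  off <- disc_offsets(radius_px)
  nr <- nrow(values); nc <- ncol(values)
  pv <- pad_matrix(values, r)
  pv2 <- pad_matrix(values^2, r)
  pn <- pad_matrix(matrix(1, nr, nc), r)
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  rows <- (r + 1):(r + nr)
  cols <- (r + 1):(r + nc)
  for (k in seq_len(nrow(off))) {
    ri <- rows + off$dy[k]; ci <- cols + off$dx[k]
    s <- s + pv[ri, ci, drop = FALSE]
    s2 <- s2 + pv2[ri, ci, drop = FALSE]
    n <- n + pn[ri, ci, drop = FALSE]
  }
  m <- s / n
  v <- pmax(0, s2 / n - m^2)
  list(mean = m, sd = sqrt(v), n = n)
}

# Separable Gaussian smoothing; borders handled by zero-padding both the
# image and a ones-mask and renormalizing, i.e. a truncated-window mean.
gaussian_smooth <- function(values, sigma_px) {
  if (sigma_px <= 0) return(values)
  half <- max(1L, as.integer(ceiling(3 * sigma_px)))
  w <- exp(-((-half:half)^2) / (2 * sigma_px^2))
  smooth1d <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    nrm <- matrix(0, nrow(m), ncol(m))
    ones <- matrix(1, nrow(m), ncol(m))
    if (along_rows) {
      pm <- pad_matrix(m, half); po <- pad_matrix(ones, half)
      rows <- (half + 1):(half + nrow(m)); cols <- (half + 1):(half + ncol(m))
      for (k in seq_along(w)) {
        d <- k - half - 1L
        acc <- acc + w[k] * pm[rows + d, cols, drop = FALSE]
        nrm <- nrm + w[k] * po[rows + d, cols, drop = FALSE]
      }
    } else {
      pm <- pad_matrix(m, half); po <- pad_matrix(ones, half)
      rows <- (half + 1):(half + nrow(m)); cols <- (half + 1):(half + ncol(m))
      for (k in seq_along(w)) {
        d <- k - half - 1L
        acc <- acc + w[k] * pm[rows, cols + d, drop = FALSE]
        nrm <- nrm + w[k] * po[rows, cols + d, drop = FALSE]
      }
    }
    acc / nrm
  }
  smooth1d(smooth1d(values, TRUE), FALSE)
}

# 8-connected component labeling of a logical mask.  Adjacent foreground
# pixels (including diagonals) are joined with igraph; returns an integer
# matrix with 0 for background and labels 1..n for components.
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  compact <- integer(nr * nc)
  compact[fg] <- seq_along(fg)
  ids <- matrix(seq_len(nr * nc), nr, nc)
  edge_pairs <- function(ra, ca, rb, cb) {
    touch <- mask[ra, ca, drop = FALSE] & mask[rb, cb, drop = FALSE]
    cbind(ids[ra, ca, drop = FALSE][touch], ids[rb, cb, drop = FALSE][touch])
  }
  ep <- list()
  if (nc > 1L) ep[[length(ep) + 1L]] <- edge_pairs(1:nr, 1:(nc - 1), 1:nr, 2:nc)
  if (nr > 1L) ep[[length(ep) + 1L]] <- edge_pairs(1:(nr - 1), 1:nc, 2:nr, 1:nc)
  if (nr > 1L && nc > 1L) {
    ep[[length(ep) + 1L]] <- edge_pairs(1:(nr - 1), 1:(nc - 1), 2:nr, 2:nc)
    ep[[length(ep) + 1L]] <- edge_pairs(2:nr, 1:(nc - 1), 1:(nr - 1), 2:nc)
  }
  edges <- do.call(rbind, ep)
  if (is.null(edges) || nrow(edges) == 0L) {
    labels[fg] <- seq_along(fg)
    return(labels)
  }
  g <- igraph::make_graph(edges = as.vector(t(matrix(compact[edges], ncol = 2))),
                          n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  labels
}

# Deterministic sub-stream seed derivation (kept within 32-bit signed range).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1099087 * as.numeric(k)) %% 2147483647)
}
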