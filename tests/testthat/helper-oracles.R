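# Independent brute-force oracles used to validate the package's
# thresholding and component machinery. These deliberately re-derive each
# quantity from first principles (per-candidate entropy sweeps, per-pixel
# window enumeration, BFS flood fill) rather than reusing package internals.

# Exhaustive Kapur maximum-entropy sweep over all 256 candidate thresholds.
oracle_max_entropy <- function(q8) {
  h <- tabulate(as.integer(q8) + 1L, nbins = 256L)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    hb <- h[1:(t + 1)]; hf <- h[(t + 2):256]
    nb <- sum(hb); nf <- sum(hf)
    if (nb == 0 || nf == 0) next
    pb <- hb[hb > 0] / nb
    pf <- hf[hf > 0] / nf
    tot <- -sum(pb * log(pb)) - sum(pf * log(pf))
    if (tot > best) { best <- tot; best_t <- t }
  }
  best_t
}

# Per-pixel window enumeration of the Phansalkar decision (truncated
# circular windows, population SD).
oracle_phansalkar <- function(x, radius = 3, p = 2, q = 10, k = 0.25,
                              R = 0.5) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  off <- expand.grid(di = -radius:radius, dj = -radius:radius)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off$di; jj <- j + off$dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    vals <- x[cbind(ii[ok], jj[ok])]
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    out[i, j] <- x[i, j] <= m * (1 + p * exp(-q * m) + k * (s / R - 1))
  }
  out
}

# BFS flood-fill 8-connected labeling (reference for component areas).
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      pnow <- queue[1]; queue <- queue[-1]
      i <- (pnow - 1L) %% nr + 1L; j <- (pnow - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- c(queue, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  lab
}

# Half-peak footprint of a planted drusen layout (truth operand for the
# mask-recovery Dice).
half_peak_footprint <- function(drusen_spec, shape, pitch_um) {
  hp <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(drusen_spec))) {
    d1 <- dome_field(drusen_spec[i, ], shape, pitch_um)
    hp <- hp | (d1 >= 0.5 * drusen_spec$peak_um[i])
  }
  hp
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
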