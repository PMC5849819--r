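# Independent brute-force oracles. These deliberately use different
# algorithmic expressions than the package implementation so that agreement
# is evidence, not tautology.

# Pixel-wise median by explicit per-pixel sort-and-pick.
oracle_median_image <- function(frames) {
  d <- dim(frames[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- sort(vapply(frames, function(f) f[i, j], numeric(1)))
      k <- length(v)
      out[i, j] <- if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
    }
  }
  out
}

# Polynomial residual via explicit normal equations. The abscissa is centred
# and scaled for conditioning; the residual of a polynomial least-squares fit
# does not depend on the basis.
oracle_poly_residual <- function(curve, order) {
  n <- length(curve)
  x <- (seq_len(n) - (n + 1) / 2) / n
  X <- outer(x, 0:order, "^")
  beta <- solve(t(X) %*% X, t(X) %*% curve)
  as.vector(curve - X %*% beta)
}

# Exhaustive local-maximum scan with plateau-first convention.
oracle_peak_positions <- function(curve) {
  n <- length(curve)
  pos <- integer(0)
  for (i in 2:(n - 1)) {
    if (curve[i] <= curve[i - 1]) next
    # plateau: run of equal values starting at i
    j <- i
    while (j < n && curve[j + 1] == curve[i]) j <- j + 1
    if (j < n && curve[j + 1] < curve[i]) pos <- c(pos, i)
  }
  pos
}

# Prominence and half-prominence width computed via vectorized range scans.
oracle_peak_width <- function(curve, p) {
  n <- length(curve)
  h <- curve[p]
  higher_left <- which(curve[seq_len(p - 1)] > h)
  lo <- if (length(higher_left)) max(higher_left) + 1 else 1
  higher_right <- which(curve[(p + 1):n] > h)
  hi <- if (length(higher_right)) p + min(higher_right) - 1 else n
  left_base <- min(curve[lo:p])
  right_base <- min(curve[p:hi])
  prom <- h - max(left_base, right_base)
  ref <- h - prom / 2
  xl <- lo
  for (i in p:(lo + 1)) {
    if (curve[i - 1] < ref) {
      xl <- (i - 1) + (ref - curve[i - 1]) / (curve[i] - curve[i - 1])
      break
    }
  }
  if (p == lo) xl <- lo
  xr <- hi
  if (p < hi) {
    for (i in p:(hi - 1)) {
      if (curve[i + 1] < ref) {
        xr <- i + (curve[i] - ref) / (curve[i] - curve[i + 1])
        break
      }
    }
  }
  xr - xl
}

# Trapezoid rule by explicit panel summation.
oracle_trapz <- function(y) {
  total <- 0
  for (i in seq_len(length(y) - 1)) total <- total + (y[i] + y[i + 1]) / 2
  total
}

# 8-connected component labeling by BFS flood fill (small images only).
oracle_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  current <- 0L
  for (si in seq_len(nrow(mask))) {
    for (sj in seq_len(ncol(mask))) {
      if (!mask[si, sj] || lab[si, sj] != 0L) next
      current <- current + 1L
      queue <- list(c(si, sj))
      lab[si, sj] <- current
      while (length(queue) > 0) {
        px <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- px[1] + di; nj <- px[2] + dj
          if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- current
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}
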