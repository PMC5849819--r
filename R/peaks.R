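#' Detect peaks in a detection curve
#'
#' A peak is a sample strictly greater than both neighbors; for a flat-topped
#' plateau the first sample of the plateau is reported. Endpoints are never
#' peaks. For each peak the raw curve value is returned as its height, its
#' prominence is computed (height above the higher of the two bases, where a
#' base is the minimum between the peak and the nearest higher sample or the
#' curve end on that side), and its width is the full width at half
#' prominence, measured in columns with linear interpolation at the crossings.
#'
#' @param curve Numeric vector of finite values.
#' @return A `peak_set`: data frame with columns `position`, `height`,
#'   `width`, `prominence` (zero rows if no peaks).
#' @export
detect_peaks <- function(curve) {
  stopifnot(is.numeric(curve), all(is.finite(curve)))
  n <- length(curve)
  positions <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (curve[i] > curve[i - 1L]) {
      j <- i
      while (j < n && curve[j + 1L] == curve[i]) j <- j + 1L
      if (j < n && curve[j + 1L] < curve[i]) positions <- c(positions, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(positions) == 0) {
    return(empty_peak_set())
  }
  res <- lapply(positions, function(p) peak_geometry(curve, p))
  out <- do.call(rbind, res)
  structure(as.data.frame(out), class = c("peak_set", "data.frame"))
}

empty_peak_set <- function() {
  structure(
    data.frame(position = integer(0), height = numeric(0), width = numeric(0),
               prominence = numeric(0)),
    class = c("peak_set", "data.frame")
  )
}

# Prominence window, prominence and half-prominence width for one peak.
peak_geometry <- function(curve, p) {
  n <- length(curve)
  h <- curve[p]
  # left base: minimum between the peak and the nearest strictly higher
  # sample to the left (or the start of the curve)
  lo <- p
  left_min <- h
  i <- p - 1L
  while (i >= 1L && curve[i] <= h) {
    if (curve[i] < left_min) left_min <- curve[i]
    i <- i - 1L
  }
  left_end <- i + 1L
  i <- p + 1L
  right_min <- h
  while (i <= n && curve[i] <= h) {
    if (curve[i] < right_min) right_min <- curve[i]
    i <- i + 1L
  }
  right_end <- i - 1L
  prominence <- h - max(left_min, right_min)
  ref <- h - prominence / 2
  # crossings of the reference height, bounded by the prominence window;
  # linear interpolation between the bracketing samples
  i <- p
  while (i > left_end && curve[i - 1L] >= ref) i <- i - 1L
  if (i > left_end) {
    xl <- (i - 1L) + (ref - curve[i - 1L]) / (curve[i] - curve[i - 1L])
  } else {
    xl <- left_end
  }
  i <- p
  while (i < right_end && curve[i + 1L] >= ref) i <- i + 1L
  if (i < right_end) {
    xr <- i + (curve[i] - ref) / (curve[i] - curve[i + 1L])
  } else {
    xr <- right_end
  }
  c(position = p, height = h, width = max(xr - xl, 0), prominence = prominence)
}

#' Build a sum-of-Gaussians curve from selected peaks
#'
#' Each selected peak contributes
#' `height_k * exp(-((x - pos_k) / (width_k / 2))^2)` evaluated at the integer
#' columns `1..length`, so the contribution drops to `height_k * exp(-1)` one
#' half-width away from the peak centre. An empty peak set yields the zero
#' curve.
#'
#' @param peaks A `peak_set` or data frame with columns `position`, `height`,
#'   `width`.
#' @param length Output curve length (number of elements).
#' @return Numeric vector of length `length`.
#' @export
gaussian_peak_vector <- function(peaks, length) {
  x <- seq_len(length)
  f <- numeric(length)
  if (nrow(peaks) == 0) return(f)
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  if (any(peaks$position < 1 | peaks$position > length)) {
    stop("peak positions must lie within the curve domain")
  }
  for (k in seq_len(nrow(peaks))) {
    f <- f + peaks$height[k] *
      exp(-((x - peaks$position[k]) / (peaks$width[k] / 2))^2)
  }
  f
}
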