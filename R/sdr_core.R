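# Systematic Dark Region (SDR) detection: from a stack of resized B-mode
# images, three analysis paths produce candidate detection curves that are
# combined by a pointwise maximum into one SDR curve whose normalized
# trapezoidal area is the scalar nonuniformity indicator.
#
#   green path - narrow streaks at a fixed lateral position: repeated median
#                images of random subsets, column-wise mean of the superficial
#                band, inversion, polynomial baseline subtraction and peak
#                detection; peaks recurring across repetitions above t_green
#                are rendered as Gaussians.
#   red path   - broader, more diffuse streaks: median of the whole stack,
#                inverted band mean, polynomial baseline subtraction,
#                thresholding at t_red.
#   blue path  - darkening at the lateral endpoints, where a polynomial
#                baseline would absorb the defect: inverted band mean without
#                baseline subtraction, thresholded at t_blue within the outer
#                p_include percent of columns.

#' Subtract each row's mean from every frame
#'
#' Centers every row of every frame at zero, removing the depth-dependent
#' brightness profile so that subsequent column statistics compare lateral
#' positions only. Output frames are signed.
#'
#' @param stack An [image_stack()].
#' @return An `image_stack` of signed frames with all row means zero.
#' @export
subtract_row_means <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  image_stack(lapply(stack$frames, function(f) f - rowMeans(f)))
}

#' Pixel-wise median of a set of frames
#'
#' For an even number of frames the mean of the two middle values is used.
#'
#' @param frames List of equal-sized numeric matrices, or an `image_stack`.
#' @return Numeric matrix of the same size.
#' @export
median_image <- function(frames) {
  if (inherits(frames, "image_stack")) frames <- frames$frames
  if (length(frames) == 0) stop("median_image needs at least one frame")
  d <- dim(frames[[1]])
  m <- vapply(frames, as.vector, numeric(prod(d)))
  if (length(frames) == 1) return(frames[[1]])
  matrix(matrixStats::rowMedians(m), d[1], d[2])
}

#' Column-wise mean of a superficial row band
#'
#' @param image Numeric matrix (signed values allowed).
#' @param r_upper,r_lower First and last row of the band (1-based, inclusive).
#' @return Numeric vector with one value per column.
#' @export
column_wise_mean <- function(image, r_upper, r_lower) {
  stopifnot_matrix(image)
  if (r_upper < 1 || r_lower > nrow(image) || r_upper > r_lower) {
    stop(sprintf("row band %d-%d outside image with %d rows",
                 r_upper, r_lower, nrow(image)))
  }
  colMeans(image[r_upper:r_lower, , drop = FALSE])
}

#' Subtract a least-squares polynomial baseline from a curve
#'
#' Fits a polynomial of the given order by least squares, with the abscissa
#' rescaled to \[-1, 1\] for numerical conditioning (the fit itself is
#' unchanged by the rescaling), and returns the residual.
#'
#' @param curve Numeric vector.
#' @param order Polynomial order (>= 0); must be smaller than the curve length.
#' @return Residual vector `curve - fit`.
#' @export
baseline_subtract <- function(curve, order) {
  n <- length(curve)
  if (n <= order) stop("curve too short for a polynomial of order ", order)
  x <- seq(-1, 1, length.out = n)
  X <- outer(x, 0:order, "^")
  fit <- stats::lm.fit(X, curve)
  curve - as.vector(X %*% fit$coefficients)
}

# Band matrix: (band_rows * ncol) x n_frames matrix of the row-mean-subtracted
# superficial band of every frame; the working representation for all three
# paths (only the band contributes to the column-wise means).
band_matrix <- function(centered, params) {
  rows <- params$r_upper:params$r_lower
  if (params$r_lower > centered$nrow) {
    stop(sprintf("row band %d-%d outside frames with %d rows",
                 params$r_upper, params$r_lower, centered$nrow))
  }
  vapply(centered$frames,
         function(f) as.vector(f[rows, , drop = FALSE]),
         numeric(length(rows) * centered$ncol))
}

band_cwm <- function(band_vec, band_rows, ncols) {
  colMeans(matrix(band_vec, band_rows, ncols))
}

#' Narrow-streak (green) detection path
#'
#' For each of `n_rep` repetitions, draws `n_select` frames without
#' replacement, forms their median image, takes the inverted column-wise mean
#' of the superficial band and subtracts a polynomial baseline of order
#' `o_poly_green`, then detects peaks. Peaks are clustered across repetitions
#' by position (single-linkage, gap <= 1 column); each cluster's height and
#' width are averaged over the repetitions in which it appears, and clusters
#' with mean height above `t_green` are rendered as a sum of Gaussians via
#' [gaussian_peak_vector()]. Sampling is driven by `params$seed`, so repeated
#' runs are identical.
#'
#' @param stack An [image_stack()] of row-mean-subtracted frames (see
#'   [subtract_row_means()]); the full stack of `n_stack` frames.
#' @param params An [sdr_params()].
#' @return Detection curve (one value per column), zero where nothing was
#'   detected.
#' @export
green_path <- function(stack, params) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "sdr_params"))
  green_path_from_band(band_matrix(stack, params),
                       params$r_lower - params$r_upper + 1L,
                       stack$ncol, length(stack$frames), params)
}

green_path_from_band <- function(bm, band_rows, ncols, n_frames, params) {
  if (params$n_select > n_frames) {
    stop(sprintf("n_select = %d exceeds stack size %d", params$n_select, n_frames))
  }
  all_peaks <- with_seed(params$seed, {
    reps <- vector("list", params$n_rep)
    for (r in seq_len(params$n_rep)) {
      idx <- sample.int(n_frames, params$n_select)
      med <- matrixStats::rowMedians(bm[, idx, drop = FALSE])
      curve <- -band_cwm(med, band_rows, ncols)
      resid <- baseline_subtract(curve, params$o_poly_green)
      pk <- detect_peaks(resid)
      reps[[r]] <- pk
    }
    do.call(rbind, reps)
  })
  if (is.null(all_peaks) || nrow(all_peaks) == 0) return(numeric(ncols))
  ord <- order(all_peaks$position)
  all_peaks <- all_peaks[ord, , drop = FALSE]
  # single-linkage position clusters: break where consecutive sorted
  # positions are more than one column apart
  cluster <- cumsum(c(1L, diff(all_peaks$position) > 1L))
  agg <- data.frame(
    position = round(tapply(all_peaks$position, cluster, mean)),
    height = as.numeric(tapply(all_peaks$height, cluster, mean)),
    width = as.numeric(tapply(all_peaks$width, cluster, mean))
  )
  selected <- agg[agg$height > params$t_green & agg$width > 0, , drop = FALSE]
  gaussian_peak_vector(selected, ncols)
}

#' Broad-streak (red) detection path
#'
#' Subtracts a polynomial baseline of order `o_poly_red` from the inverted
#' column-wise mean of the full-stack median image and keeps residual values
#' above `t_red`; everything else is set to zero.
#'
#' @param inverted_cwm Inverted (negated) column-wise mean of the superficial
#'   band of the full-stack median image.
#' @param params An [sdr_params()].
#' @return Detection curve.
#' @export
red_path <- function(inverted_cwm, params) {
  resid <- baseline_subtract(inverted_cwm, params$o_poly_red)
  resid[resid <= params$t_red] <- 0
  resid
}

#' Endpoint (blue) detection path
#'
#' Keeps values of the inverted column-wise mean above `t_blue` within the
#' first and last `floor(p_include / 100 * length)` columns, without any
#' baseline subtraction (a polynomial fit would absorb endpoint darkening).
#'
#' @inheritParams red_path
#' @return Detection curve.
#' @export
blue_path <- function(inverted_cwm, params) {
  n <- length(inverted_cwm)
  k <- floor(params$p_include / 100 * n)
  out <- numeric(n)
  if (k > 0) {
    zone <- c(seq_len(k), seq.int(n - k + 1L, n))
    keep <- zone[inverted_cwm[zone] > params$t_blue]
    out[keep] <- inverted_cwm[keep]
  }
  out
}

#' Combine the three detection paths into an SDR curve
#'
#' Takes the pointwise maximum of the green, red and blue curves, zeroes the
#' first and last `floor(p_exclude / 100 * length)` columns (border streaks
#' appear even for healthy transducers), and computes the normalized
#' trapezoidal area.
#'
#' @param green,red,blue Equal-length detection curves.
#' @param params An [sdr_params()].
#' @param index Optional index/timestamp of the newest contributing image.
#' @return An `sdr_curve`: list with `values` (nonnegative, one per column)
#'   and `area`.
#' @export
combine_paths <- function(green, red, blue, params, index = NA) {
  n <- length(green)
  if (length(red) != n || length(blue) != n) {
    stop("path curves must have equal length")
  }
  values <- pmax(green, red, blue, 0)
  ex <- floor(params$p_exclude / 100 * n)
  if (ex > 0) {
    values[c(seq_len(ex), seq.int(n - ex + 1L, n))] <- 0
  }
  sdr_curve(values, index = index)
}

#' Construct an SDR curve object
#'
#' @param values Nonnegative per-column detection values (one per element).
#' @param index Optional index/timestamp of the newest contributing image.
#' @return An object of class `sdr_curve` with fields `values` and `area`
#'   (trapezoidal area normalized by the element count).
#' @export
sdr_curve <- function(values, index = NA) {
  stopifnot(is.numeric(values), all(values >= 0))
  structure(list(values = values, area = sdr_area(values, length(values)),
                 index = index),
            class = "sdr_curve")
}

#' @export
print.sdr_curve <- function(x, ...) {
  cat(sprintf("SDR curve: %d elements, area %.4f, %d nonzero column(s)\n",
              length(x$values), x$area, sum(x$values > 0)))
  invisible(x)
}

#' Normalized trapezoidal area under a curve
#'
#' Trapezoidal integration with unit column spacing, divided by the element
#' count, giving the scalar nonuniformity indicator.
#'
#' @param curve Numeric vector of per-column values.
#' @param element_count Number of transducer elements (= curve length).
#' @return Scalar area.
#' @export
sdr_area <- function(curve, element_count) {
  if (length(curve) != element_count) {
    stop("curve length must equal the element count")
  }
  trapz_unit(curve) / element_count
}

#' Compute one SDR curve from an image stack
#'
#' Runs the full three-path algorithm: row-mean subtraction, the green path on
#' repeated random-subset medians, and the red and blue paths on the median of
#' all frames, combined by a pointwise maximum with endpoint exclusion.
#' Deterministic given `params$seed`.
#'
#' @param stack An [image_stack()] of exactly `params$n_stack` resized frames.
#' @param params An [sdr_params()].
#' @param index Optional index/timestamp of the newest contributing image.
#' @return An `sdr_curve`.
#' @export
compute_sdr_curve <- function(stack, params = sdr_params(), index = NA) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "sdr_params"))
  if (length(stack$frames) != params$n_stack) {
    stop(sprintf("stack holds %d frames but params$n_stack = %d",
                 length(stack$frames), params$n_stack))
  }
  centered <- subtract_row_means(stack)
  bm <- band_matrix(centered, params)
  band_rows <- params$r_lower - params$r_upper + 1L
  ncols <- stack$ncol

  green <- green_path_from_band(bm, band_rows, ncols, params$n_stack, params)

  full_median <- if (ncol(bm) == 1) bm[, 1] else matrixStats::rowMedians(bm)
  inverted_cwm <- -band_cwm(full_median, band_rows, ncols)
  red <- red_path(inverted_cwm, params)
  blue <- blue_path(inverted_cwm, params)

  combine_paths(green, red, blue, params, index = index)
}
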