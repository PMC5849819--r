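# B-mode extraction: locate the largest connected region of nonzero pixels in
# the stored grayscale frame, take its outer corners, check the physical
# width against the transducer's accepted range, and resize to
# element_count x resized_height so one column corresponds to one element.

# 8-connected component labeling on a nonzero mask, run-based union-find.
# Returns per-row runs (start, end, row, label-root) and component areas.
label_components8 <- function(gray) {
  nr <- nrow(gray)
  runs_row <- integer(0); runs_start <- integer(0); runs_end <- integer(0)
  for (r in seq_len(nr)) {
    rl <- rle(gray[r, ] != 0)
    if (!any(rl$values)) next
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs_row <- c(runs_row, rep.int(r, sum(keep)))
    runs_start <- c(runs_start, starts[keep])
    runs_end <- c(runs_end, ends[keep])
  }
  n_runs <- length(runs_row)
  if (n_runs == 0) return(NULL)
  parent <- seq_len(n_runs)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  union_runs <- function(i, j) {
    ri <- find_root(i); rj <- find_root(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  prev_idx <- integer(0)
  row_of <- split(seq_len(n_runs), runs_row)
  rows_present <- as.integer(names(row_of))
  for (k in seq_along(rows_present)) {
    cur_idx <- row_of[[k]]
    if (k > 1 && rows_present[k] == rows_present[k - 1] + 1L) {
      # 8-connectivity: runs touch if column ranges overlap when the current
      # run is widened by one column on each side
      for (i in cur_idx) {
        lo <- runs_start[i] - 1L; hi <- runs_end[i] + 1L
        for (j in prev_idx) {
          if (runs_start[j] <= hi && runs_end[j] >= lo) union_runs(i, j)
        }
      }
    }
    prev_idx <- cur_idx
  }
  roots <- vapply(seq_len(n_runs), find_root, integer(1))
  areas <- tapply(runs_end - runs_start + 1L, roots, sum)
  list(row = runs_row, start = runs_start, end = runs_end,
       root = roots, areas = areas)
}

#' Locate the B-mode rectangle in a stored grayscale frame
#'
#' Selects the largest 8-connected component of nonzero pixels, zeroes every
#' other pixel, and determines the outer corners of the surviving region by
#' separating zero-filled from nonzero fields: the top and bottom rows are the
#' first and last rows containing region pixels, and the left and right
#' columns are taken from the most superficial 5% of the region's rows, so
#' that regions narrowing with depth (virtually convex displays) are extracted
#' as a rectangle with the width of their most superficial part and their full
#' height.
#'
#' @param gray Grayscale matrix of the stored frame.
#' @return List with `corners` (`top`, `bottom`, `left`, `right`; 1-based,
#'   inclusive), `cleaned` (the frame with all other components zeroed) and
#'   `area` (pixel count of the selected component).
#' @export
find_bmode_region <- function(gray) {
  stopifnot_matrix(gray)
  lab <- label_components8(gray)
  if (is.null(lab)) stop("no B-mode region found: image has no nonzero pixels")
  best_root <- as.integer(names(lab$areas)[which.max(lab$areas)])
  sel <- lab$root == best_root
  rows <- lab$row[sel]; starts <- lab$start[sel]; ends <- lab$end[sel]

  cleaned <- matrix(0, nrow(gray), ncol(gray))
  for (i in seq_along(rows)) {
    cleaned[rows[i], starts[i]:ends[i]] <- gray[rows[i], starts[i]:ends[i]]
  }

  top <- min(rows); bottom <- max(rows)
  band_depth <- max(1L, ceiling(0.05 * (bottom - top + 1L)))
  in_band <- rows <= top + band_depth - 1L
  corners <- list(top = top, bottom = bottom,
                  left = min(starts[in_band]), right = max(ends[in_band]))
  list(corners = corners, cleaned = cleaned,
       area = sum(ends - starts + 1L))
}

#' Check for lateral zoom via the physical width
#'
#' A laterally zoomed image breaks the column-to-element correspondence, so
#' the physical width of the extracted rectangle (number of columns times the
#' pixel pitch) must match the transducer aperture. The DICOM ultrasound
#' region calibration stores `PhysicalDeltaX` in cm per pixel; it is converted
#' to mm here (`unit_scale = 10`), overridable per scanner.
#'
#' @param corners Corner list from [find_bmode_region()].
#' @param physical_delta_x Pixel pitch from the DICOM region calibration.
#' @param profile A [transducer_profile()] supplying the accepted closed
#'   interval in mm.
#' @param unit_scale Multiplier from the tag's native unit to mm (default 10,
#'   i.e. cm to mm).
#' @return List with `accept` (logical), `physical_width_mm` and `reason`
#'   (`NA` if accepted, else `"width_over"`, `"width_under"` or
#'   `"no_calibration"`).
#' @export
check_lateral_zoom <- function(corners, physical_delta_x, profile,
                               unit_scale = 10) {
  stopifnot(inherits(profile, "transducer_profile"))
  if (is.null(physical_delta_x) || is.na(physical_delta_x) ||
      physical_delta_x <= 0) {
    return(list(accept = FALSE, physical_width_mm = NA_real_,
                reason = "no_calibration"))
  }
  width_px <- corners$right - corners$left + 1L
  width_mm <- width_px * physical_delta_x * unit_scale
  lo <- profile$accepted_width_mm[1]; hi <- profile$accepted_width_mm[2]
  if (width_mm < lo) {
    list(accept = FALSE, physical_width_mm = width_mm, reason = "width_under")
  } else if (width_mm > hi) {
    list(accept = FALSE, physical_width_mm = width_mm, reason = "width_over")
  } else {
    list(accept = TRUE, physical_width_mm = width_mm, reason = NA_character_)
  }
}

# Keys cubic convolution kernel, a = -0.5 (the classic bicubic interpolant).
keys_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Dense (n_out x n_in) interpolation weight matrix for one axis. Output pixel
# centres map to input coordinates by (i - 0.5) * n_in / n_out + 0.5; the four
# surrounding taps are weighted by the Keys kernel with indices clamped at the
# edges (kernel weights always sum to 1, so constants are preserved exactly).
bicubic_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    base <- floor(src)
    taps <- (base - 1):(base + 2)
    w <- keys_kernel(src - taps)
    taps <- pmin(pmax(taps, 1), n_in)
    for (k in seq_along(taps)) W[i, taps[k]] <- W[i, taps[k]] + w[k]
  }
  W
}

#' Bicubic image resize
#'
#' Separable cubic convolution (Keys kernel, a = -0.5) with clamped edges,
#' applied as row and column weight-matrix products.
#'
#' @param image Numeric matrix.
#' @param out_rows,out_cols Output dimensions (>= 2 each).
#' @return Resized numeric matrix.
#' @export
resize_bicubic <- function(image, out_rows, out_cols) {
  stopifnot_matrix(image)
  if (nrow(image) < 2 || ncol(image) < 2) {
    stop("cannot resize a degenerate (<= 1 pixel per axis) image")
  }
  Wr <- bicubic_weights(out_rows, nrow(image))
  Wc <- bicubic_weights(out_cols, ncol(image))
  Wr %*% image %*% t(Wc)
}

#' Resize an extracted B-mode image to element coordinates
#'
#' Bicubic resize to exactly `element_count` columns by `resized_height` rows,
#' clipped back to the \[0, 255\] gray range, so each column of the result
#' corresponds to one transducer element.
#'
#' @param extract A `bmode_extract` (see [extract_bmode()]) or a plain
#'   grayscale matrix of the cropped B-mode image.
#' @param profile A [transducer_profile()].
#' @return Numeric matrix of size `resized_height` x `element_count`.
#' @export
resize_bmode <- function(extract, profile) {
  stopifnot(inherits(profile, "transducer_profile"))
  img <- if (is.matrix(extract)) extract else extract$image
  clip255(resize_bicubic(img, profile$resized_height, profile$element_count))
}

#' Extract, validate and resize the B-mode image of one stored frame
#'
#' Orchestrates [find_bmode_region()], [check_lateral_zoom()] and
#' [resize_bmode()]. Every input yields exactly one outcome: an accepted
#' extract, or a rejection with one of the enumerated reasons `"no_region"`,
#' `"no_calibration"`, `"width_under"`, `"width_over"`.
#'
#' @param gray Grayscale stored frame (see [to_grayscale()]).
#' @param physical_delta_x Pixel pitch from the DICOM region calibration
#'   (cm per pixel by default; see `unit_scale`).
#' @param profile A [transducer_profile()].
#' @param unit_scale Multiplier from the tag's unit to mm (default cm -> mm).
#' @return List with `status` (`"accepted"` or `"rejected"`); when accepted,
#'   `image` (the resized matrix) and `extract` (a `bmode_extract` with the
#'   cropped image, `corners` and `physical_width_mm`); when rejected,
#'   `reason`.
#' @export
extract_bmode <- function(gray, physical_delta_x, profile, unit_scale = 10) {
  region <- tryCatch(find_bmode_region(gray), error = function(e) NULL)
  if (is.null(region)) {
    return(list(status = "rejected", reason = "no_region"))
  }
  zoom <- check_lateral_zoom(region$corners, physical_delta_x, profile,
                             unit_scale)
  if (!zoom$accept) {
    return(list(status = "rejected", reason = zoom$reason,
                physical_width_mm = zoom$physical_width_mm))
  }
  cr <- region$corners
  cropped <- region$cleaned[cr$top:cr$bottom, cr$left:cr$right, drop = FALSE]
  extract <- structure(
    list(image = cropped, corners = cr,
         physical_width_mm = zoom$physical_width_mm),
    class = "bmode_extract"
  )
  list(status = "accepted", image = resize_bmode(extract, profile),
       extract = extract)
}
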