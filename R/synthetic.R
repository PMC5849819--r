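#' Describe an injected transducer defect
#'
#' A defect is rendered as a vertical band of reduced gray level, maximal at
#' the top (superficial) row and attenuating linearly with depth. Sharp
#' single-element dropouts are one column wide; delamination-like faults span
#' several columns. An intermittent fault (loose cable, bad connector) is
#' absent in a random fraction of frames.
#'
#' @param center_column Column index (1-based) of the band centre, in
#'   resized-image coordinates where one column is one element.
#' @param width_columns Band width in columns (integer >= 1).
#' @param strength Gray-level depression at the top row, on the 0-255 scale.
#' @param depth_decay Fraction per row by which the depression attenuates with
#'   depth; 0 keeps it constant, 1/500 makes it vanish at the bottom of a
#'   500-row image.
#' @param intermittency Fraction in \[0, 1\] of frames in which the defect is
#'   absent; 0 = persistent, 1 = never present.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(center_column, width_columns = 1L, strength = 20,
                        depth_decay = 0, intermittency = 0) {
  stopifnot(
    center_column >= 1, width_columns >= 1, strength >= 0,
    depth_decay >= 0, intermittency >= 0, intermittency <= 1
  )
  structure(
    list(center_column = as.integer(center_column),
         width_columns = as.integer(width_columns),
         strength = as.numeric(strength),
         depth_decay = as.numeric(depth_decay),
         intermittency = as.numeric(intermittency)),
    class = "defect_spec"
  )
}

#' Clinical-like background model for synthetic frames
#'
#' Emulates the defining statistics of stored clinical B-mode frames as seen
#' by the detection algorithm: large frame-to-frame anatomical variability
#' (smooth random radial bumps) on a mean gray level, with multiplicative
#' Rayleigh-like speckle. Individual frames differ strongly, but the expected
#' column-wise mean over many frames is flat, so anatomy cancels in a median
#' image while systematic dark bands persist.
#'
#' @param mean_level Mean background gray level (0-255).
#' @param blob_count Number of smooth random structures per frame.
#' @param blob_amplitude Gray-level range of the structures.
#' @param speckle_sigma Scale of the multiplicative speckle (0 = noise-free).
#' @param seed Integer seed; frame `i` is generated from a seed derived from
#'   `seed` and `i`, so stacks are reproducible and individual frames can be
#'   regenerated in isolation.
#' @return An object of class `background_model`.
#' @export
background_model <- function(mean_level = 110, blob_count = 6L,
                             blob_amplitude = 60, speckle_sigma = 0.25,
                             seed = 1L) {
  stopifnot(mean_level >= 0, mean_level <= 255, blob_count >= 0,
            blob_amplitude >= 0, speckle_sigma >= 0)
  structure(
    list(mean_level = as.numeric(mean_level), blob_count = as.integer(blob_count),
         blob_amplitude = as.numeric(blob_amplitude),
         speckle_sigma = as.numeric(speckle_sigma), seed = as.integer(seed)),
    class = "background_model"
  )
}

# Unit-mean Rayleigh deviates: sigma * sqrt(-2 log U) with sigma chosen so
# E[R] = 1. The fully developed speckle envelope is Rayleigh distributed;
# speckle_sigma blends it with the noise-free field.
rayleigh_unit_mean <- function(n) {
  sqrt(-2 * log(stats::runif(n))) / sqrt(pi / 2)
}

#' Generate one synthetic B-mode frame
#'
#' Draws a background realization for `frame_index`, applies multiplicative
#' speckle, then subtracts each defect that is present in this frame as a
#' column-band gray-level depression (maximal at row 1, decaying with depth)
#' before clipping to \[0, 255\]. Given the same `background` (including its
#' seed) and `frame_index`, the frame is bit-reproducible, and the background
#' realization is identical whether or not defects are supplied.
#'
#' @param background A [background_model()].
#' @param defects List of [defect_spec()] objects (possibly empty).
#' @param frame_index Integer index of the frame within its stack.
#' @param nrow,ncol Frame dimensions; typically a profile's
#'   `resized_height` x `element_count`.
#' @return Numeric matrix (`nrow` x `ncol`) of gray levels in \[0, 255\].
#' @export
generate_frame <- function(background, defects = list(), frame_index = 1L,
                           nrow = 500L, ncol = 336L) {
  stopifnot(inherits(background, "background_model"), nrow >= 1, ncol >= 1)
  if (inherits(defects, "defect_spec")) defects <- list(defects)
  for (d in defects) {
    cols <- defect_columns(d)
    if (any(cols < 1L) || any(cols > ncol)) {
      bad <- cols[cols < 1L | cols > ncol][1]
      stop(sprintf("defect column %d outside frame width %d", bad, ncol))
    }
  }
  with_seed(derive_seed(background$seed, frame_index), {
    img <- matrix(background$mean_level, nrow, ncol)
    if (background$blob_count > 0 && background$blob_amplitude > 0) {
      r0 <- stats::runif(background$blob_count, 1, nrow)
      c0 <- stats::runif(background$blob_count, 1, ncol)
      rad <- stats::runif(background$blob_count, 0.08, 0.35) * min(nrow, ncol)
      amp <- stats::runif(background$blob_count, -1, 1) * background$blob_amplitude
      rows <- seq_len(nrow)
      cols <- seq_len(ncol)
      for (b in seq_len(background$blob_count)) {
        img <- img + amp[b] *
          exp(-(outer((rows - r0[b])^2, (cols - c0[b])^2, "+")) / (2 * rad[b]^2))
      }
    }
    if (background$speckle_sigma > 0) {
      img <- img * (1 + background$speckle_sigma * (rayleigh_unit_mean(nrow * ncol) - 1))
    }
    for (d in defects) {
      present <- stats::runif(1) >= d$intermittency
      if (present && d$strength > 0) {
        depth_profile <- d$strength * pmax(0, 1 - d$depth_decay * (seq_len(nrow) - 1))
        img[, defect_columns(d)] <- img[, defect_columns(d)] - depth_profile
      }
    }
    clip255(img)
  })
}

defect_columns <- function(d) {
  d$center_column - floor((d$width_columns - 1) / 2) + seq_len(d$width_columns) - 1L
}

#' Generate a stack of synthetic frames
#'
#' @inheritParams generate_frame
#' @param n Number of frames (>= 1).
#' @param profile A [transducer_profile()]; fixes the frame size to
#'   `resized_height` x `element_count`.
#' @param seed Optional seed overriding `background$seed`, so one background
#'   description can produce many independent stacks.
#' @return An `image_stack`: list of `n` frames with identical dimensions.
#' @export
generate_stack <- function(n, profile, background, defects = list(), seed = NULL) {
  stopifnot(inherits(profile, "transducer_profile"))
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) background$seed <- as.integer(seed)
  frames <- lapply(seq_len(n), function(i) {
    generate_frame(background, defects, frame_index = i,
                   nrow = profile$resized_height, ncol = profile$element_count)
  })
  image_stack(frames)
}

#' Construct an image stack from a list of equal-sized frames
#'
#' @param frames List of numeric matrices with identical dimensions, in
#'   acquisition order.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames) {
  if (length(frames) == 0) stop("image stack must contain at least one frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames in a stack must share dimensions")
  }
  structure(list(frames = frames, nrow = dims[1, 1], ncol = dims[2, 1]),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d frames of %d x %d (rows x columns)\n",
              length(x$frames), x$nrow, x$ncol))
  invisible(x)
}

#' Serialize / read a ground-truth defect manifest
#'
#' The manifest accompanies each generated archive so that detection results
#' can be scored against the injected truth.
#'
#' @param defects List of [defect_spec()] objects.
#' @param path Output (or input) JSON file path.
#' @param extra Optional named list of additional fields (seed, frame counts).
#' @export
write_defect_manifest <- function(defects, path, extra = list()) {
  if (inherits(defects, "defect_spec")) defects <- list(defects)
  payload <- c(list(defects = lapply(defects, unclass)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_defect_manifest
#' @export
read_defect_manifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload$defects <- lapply(payload$defects, function(d) do.call(defect_spec, d))
  payload
}
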