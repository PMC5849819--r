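#' Transducer profiles
#'
#' A transducer profile records the geometry needed to map a stored B-mode
#' image onto transducer elements: the element count (which becomes the width
#' of the resized image, so that one column corresponds to one element), the
#' physical aperture and the accepted physical-width interval used to reject
#' laterally zoomed images.
#'
#' Two profiles ship with the package: the GE ML 6-15 (336 elements) and the
#' Philips L12-5 (256 elements), both with a 50 mm aperture and an accepted
#' width range of \[49.5, 51.5\] mm, giving resized image sizes of 336 x 500
#' and 256 x 500 (width x height).
#'
#' @param model_name Transducer model label, e.g. `"ML 6-15"`.
#' @param element_count Number of piezoelectric elements (>= 2).
#' @param aperture_mm Physical aperture in millimetres.
#' @param accepted_width_mm Closed interval `c(low, high)` in millimetres; an
#'   extracted B-mode image whose physical width falls outside it is rejected
#'   as laterally zoomed.
#' @param resized_height Height in pixels of the resized B-mode image.
#' @return An object of class `transducer_profile`.
#' @examples
#' transducer_profile("ML 6-15")
#' @export
transducer_profile <- function(model_name,
                               element_count = NULL,
                               aperture_mm = 50,
                               accepted_width_mm = c(49.5, 51.5),
                               resized_height = 500L) {
  if (is.null(element_count)) {
    reg <- profile_registry()
    if (!model_name %in% names(reg)) {
      stop("unknown transducer model '", model_name,
           "'; supply element_count or use one of: ",
           paste(names(reg), collapse = ", "))
    }
    return(reg[[model_name]])
  }
  element_count <- as.integer(element_count)
  stopifnot(
    element_count >= 2, length(accepted_width_mm) == 2,
    accepted_width_mm[1] <= accepted_width_mm[2],
    aperture_mm >= accepted_width_mm[1], aperture_mm <= accepted_width_mm[2],
    resized_height >= 2
  )
  structure(
    list(model_name = model_name, element_count = element_count,
         aperture_mm = as.numeric(aperture_mm),
         accepted_width_mm = as.numeric(accepted_width_mm),
         resized_height = as.integer(resized_height)),
    class = "transducer_profile"
  )
}

#' @rdname transducer_profile
#' @return For `profile_registry()`, a named list of the shipped profiles.
#' @export
profile_registry <- function() {
  list(
    "ML 6-15" = transducer_profile("ML 6-15", element_count = 336L),
    "L12-5"   = transducer_profile("L12-5", element_count = 256L)
  )
}

#' @export
print.transducer_profile <- function(x, ...) {
  cat(sprintf("Transducer profile '%s': %d elements, aperture %g mm,\n",
              x$model_name, x$element_count, x$aperture_mm))
  cat(sprintf("  accepted width [%g, %g] mm, resized to %d x %d (width x height)\n",
              x$accepted_width_mm[1], x$accepted_width_mm[2],
              x$element_count, x$resized_height))
  invisible(x)
}
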