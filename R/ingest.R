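#' Select usable frames from an archive
#'
#' Keeps records from the requested scanner (`StationName`) and transducer
#' (`TransducerData`) whose ultrasound-region sequence declares exactly one
#' region and whose stored width does not exceed the single-image layout of
#' that scanner. Frames with more than one region item carry Doppler curves or
#' side-by-side displays and are rejected; so are frames wider than a single
#' image. Color Doppler images without a spectral curve present as one region
#' and are kept. Records missing `StationName` are skipped with a warning and
#' tallied separately.
#'
#' @param records List of `dicom_record` objects, e.g. from [read_dicom_dir()].
#' @param station_name Scanner identifier to match exactly.
#' @param transducer_label Transducer label to match exactly; `NULL` keeps all
#'   transducers (for scanners whose archives do not populate the tag).
#' @param max_single_image_cols Largest stored width (columns) of a
#'   single-image display for this scanner layout.
#' @return List with `accepted` (list of matching records) and `report`
#'   (a `selection_report`).
#' @export
select_images <- function(records, station_name, transducer_label = NULL,
                          max_single_image_cols = Inf) {
  accepted <- list()
  n_doppler <- 0L
  n_skipped <- 0L
  n_collected <- 0L
  for (rec in records) {
    if (is.na(rec$station_name)) {
      warning(sprintf("record %s has no StationName; skipped",
                      basename(rec$path %||% "<in-memory>")), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    if (rec$station_name != station_name) next
    if (!is.null(transducer_label) && !is.na(rec$transducer_label) &&
        nzchar(rec$transducer_label) && rec$transducer_label != transducer_label) {
      next
    }
    n_collected <- n_collected + 1L
    if (rec$region_count != 1L || rec$cols > max_single_image_cols) {
      n_doppler <- n_doppler + 1L
      next
    }
    accepted[[length(accepted) + 1L]] <- rec
  }
  list(
    accepted = accepted,
    report = selection_report(n_collected = n_collected,
                              n_rejected_doppler = n_doppler,
                              n_rejected_width = 0L,
                              n_used = length(accepted),
                              n_skipped_missing_tags = n_skipped)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Selection / extraction tally for one archive pass
#'
#' Counts conserve the collected total:
#' `n_collected = n_rejected_doppler + n_rejected_width + n_used`.
#' Width rejections are filled in after the lateral-zoom check of the
#' extraction stage (see [count_width_rejections()]).
#'
#' @param n_collected Frames collected for the scanner/transducer combination.
#' @param n_rejected_doppler Frames rejected for Doppler curves or
#'   side-by-side displays.
#' @param n_rejected_width Frames rejected because the extracted B-mode width
#'   fell outside the transducer's accepted physical-width limits.
#' @param n_used Frames entering the analysis.
#' @param n_skipped_missing_tags Unreadable or tag-less records skipped before
#'   collection.
#' @return An object of class `selection_report`.
#' @export
selection_report <- function(n_collected, n_rejected_doppler, n_rejected_width,
                             n_used, n_skipped_missing_tags = 0L) {
  rep <- list(n_collected = as.integer(n_collected),
              n_rejected_doppler = as.integer(n_rejected_doppler),
              n_rejected_width = as.integer(n_rejected_width),
              n_used = as.integer(n_used),
              n_skipped_missing_tags = as.integer(n_skipped_missing_tags))
  if (rep$n_collected !=
      rep$n_rejected_doppler + rep$n_rejected_width + rep$n_used) {
    stop("selection report does not conserve the collected count")
  }
  structure(rep, class = "selection_report")
}

#' @rdname selection_report
#' @param report An existing `selection_report`.
#' @param reasons Character vector of extraction rejection reasons
#'   (`"width_over"`, `"width_under"`, `"no_calibration"`, `"no_region"`).
#' @export
count_width_rejections <- function(report, reasons) {
  n_rej <- sum(reasons %in% c("width_over", "width_under", "no_calibration",
                              "no_region"))
  selection_report(
    n_collected = report$n_collected,
    n_rejected_doppler = report$n_rejected_doppler,
    n_rejected_width = report$n_rejected_width + n_rej,
    n_used = report$n_used - n_rej,
    n_skipped_missing_tags = report$n_skipped_missing_tags
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection report\n")
  cat(sprintf("  collected:            %d\n", x$n_collected))
  cat(sprintf("  rejected (Doppler/side-by-side): %d\n", x$n_rejected_doppler))
  cat(sprintf("  rejected (width limits):         %d\n", x$n_rejected_width))
  cat(sprintf("  used:                 %d\n", x$n_used))
  if (x$n_skipped_missing_tags > 0) {
    cat(sprintf("  skipped (missing tags): %d\n", x$n_skipped_missing_tags))
  }
  invisible(x)
}

#' Convert an RGB frame to 8-bit grayscale
#'
#' Uses the Rec.601 luma weights (0.299, 0.587, 0.114), rounded to the nearest
#' integer, so gray pixels are fixed points of the conversion.
#'
#' @param rgb A rows x cols x 3 numeric array with 8-bit samples.
#' @return A rows x cols numeric matrix of gray levels.
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("expected a rows x cols x 3 RGB array, got dimensions ",
         paste(dim(rgb), collapse = " x "))
  }
  d <- dim(rgb)
  matrix(round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]),
         d[1], d[2])
}

#' Sort records chronologically by StudyDate
#'
#' Ascending by `StudyDate`, ties broken by `StudyTime`, remaining ties by
#' input order (stable). Records whose date cannot be parsed as `YYYYMMDD`
#' are excluded with a warning.
#'
#' @param records List of `dicom_record` objects.
#' @return Reordered list.
#' @export
sort_by_study_date <- function(records) {
  if (length(records) == 0) return(records)
  dates <- vapply(records, function(r) r$study_date %||% NA_character_,
                  character(1))
  times <- vapply(records, function(r) {
    t <- r$study_time %||% NA_character_
    if (is.na(t) || !nzchar(t)) "000000" else t
  }, character(1))
  parsed <- as.Date(dates, format = "%Y%m%d")
  bad <- is.na(parsed)
  if (any(bad)) {
    warning(sprintf("%d record(s) with unparseable StudyDate excluded", sum(bad)),
            call. = FALSE)
    records <- records[!bad]
    parsed <- parsed[!bad]
    times <- times[!bad]
  }
  records[order(parsed, times)]  # order() is a stable sort
}
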