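# Rolling monitoring: one state per (station, transducer model) pair holds a
# FIFO buffer of resized B-mode images; each newly stored image produces one
# SDR curve once the buffer is full, and the area series is watched for
# threshold crossings.

#' Create a rolling monitor state
#'
#' @param profile A [transducer_profile()]; fixes the expected frame size.
#' @param params An [sdr_params()].
#' @param station_name,transducer_label Identity of the monitored system.
#' @return An object of class `sdr_monitor` holding an empty buffer and an
#'   empty SDR series.
#' @export
sdr_monitor <- function(profile, params = sdr_params(),
                        station_name = NA_character_,
                        transducer_label = profile$model_name) {
  stopifnot(inherits(profile, "transducer_profile"),
            inherits(params, "sdr_params"))
  structure(
    list(profile = profile, params = params,
         station_name = station_name, transducer_label = transducer_label,
         buffer = list(), last_date = NULL,
         curves = list(), areas = numeric(0), indices = integer(0),
         n_fed = 0L),
    class = "sdr_monitor"
  )
}

#' Feed one image into the rolling stack
#'
#' Appends the image to the buffer; once the buffer holds `n_stack` images the
#' oldest is evicted first-in-first-out and one SDR curve is computed per
#' update. Before the stack is full no curve is emitted. Images must arrive in
#' non-decreasing `StudyDate` order (sort with [sort_by_study_date()] first);
#' a date regression is an error.
#'
#' @param state An `sdr_monitor`.
#' @param new_image Resized grayscale matrix of size
#'   `resized_height` x `element_count`.
#' @param date Optional acquisition date (anything `>=`-comparable) used only
#'   to assert chronological feeding.
#' @return The updated `sdr_monitor`; when a curve was emitted it is appended
#'   to `state$curves` and its area to `state$areas`.
#' @export
rolling_update <- function(state, new_image, date = NULL) {
  stopifnot(inherits(state, "sdr_monitor"))
  stopifnot_matrix(new_image, "new_image")
  pr <- state$profile
  if (nrow(new_image) != pr$resized_height || ncol(new_image) != pr$element_count) {
    stop(sprintf("image is %d x %d but the monitor expects %d x %d",
                 nrow(new_image), ncol(new_image),
                 pr$resized_height, pr$element_count))
  }
  if (!is.null(date) && !is.null(state$last_date) && date < state$last_date) {
    stop("images must be fed in non-decreasing StudyDate order")
  }
  if (!is.null(date)) state$last_date <- date
  state$n_fed <- state$n_fed + 1L
  state$buffer[[length(state$buffer) + 1L]] <- new_image
  if (length(state$buffer) > state$params$n_stack) {
    state$buffer <- state$buffer[-1L]
  }
  if (length(state$buffer) == state$params$n_stack) {
    curve <- compute_sdr_curve(image_stack(state$buffer), state$params,
                               index = state$n_fed)
    state$curves[[length(state$curves) + 1L]] <- curve
    state$areas <- c(state$areas, curve$area)
    state$indices <- c(state$indices, state$n_fed)
  }
  state
}

#' @export
print.sdr_monitor <- function(x, ...) {
  cat(sprintf("SDR monitor for station '%s', transducer '%s'\n",
              x$station_name, x$transducer_label))
  cat(sprintf("  fed %d image(s), buffer %d/%d, %d curve(s) emitted\n",
              x$n_fed, length(x$buffer), x$params$n_stack, length(x$curves)))
  if (length(x$areas) > 0) {
    cat(sprintf("  latest area %.4f, max area %.4f\n",
                x$areas[length(x$areas)], max(x$areas)))
  }
  invisible(x)
}

#' Threshold notifications on the area series
#'
#' Emits one notification per rising edge: an index where the area crosses
#' from below the threshold to at or above it (the first curve of the series
#' counts as a rising edge if already above). A persistent fault therefore
#' alerts once until it clears, avoiding alert storms in continuous
#' monitoring. The default threshold 0.75 sits inside the 0.5-1 interval that
#' detected the studied defect cases at an early stage.
#'
#' @param series An `sdr_monitor` or a numeric vector of areas.
#' @param threshold Notification level for the normalized SDR area (> 0).
#' @return Data frame with one row per notification: `curve_index`, `area`,
#'   `threshold`.
#' @export
notify <- function(series, threshold = 0.75) {
  stopifnot(threshold > 0)
  areas <- if (inherits(series, "sdr_monitor")) series$areas else as.numeric(series)
  if (length(areas) == 0) {
    return(data.frame(curve_index = integer(0), area = numeric(0),
                      threshold = numeric(0)))
  }
  above <- areas >= threshold
  rising <- above & !c(FALSE, above[-length(above)])
  idx <- which(rising)
  data.frame(curve_index = idx, area = areas[idx],
             threshold = rep(threshold, length(idx)))
}

#' Export the SDR curve surface and its rendering
#'
#' Writes the series of SDR curves as a CSV matrix (one row per curve, one
#' column per element) and, optionally, renders the surface as a heatmap
#' figure (curve index vs element), the monitoring view in which emerging,
#' intermittent and healing defects are read off as ridges.
#'
#' @param state An `sdr_monitor` with at least one emitted curve.
#' @param csv_path Output CSV path.
#' @param figure_path Optional PNG path for the rendered surface.
#' @return Invisibly, the surface matrix (curves x elements).
#' @export
export_surface <- function(state, csv_path, figure_path = NULL) {
  stopifnot(inherits(state, "sdr_monitor"))
  if (length(state$curves) == 0) stop("no SDR curves to export")
  surface <- do.call(rbind, lapply(state$curves, function(cv) cv$values))
  df <- data.frame(curve = seq_len(nrow(surface)), index = state$indices,
                   area = state$areas, surface, check.names = FALSE)
  names(df) <- c("curve", "index", "area",
                 paste0("e", seq_len(ncol(surface))))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(figure_path)) {
    grDevices::png(figure_path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(
      x = seq_len(nrow(surface)), y = seq_len(ncol(surface)), z = surface,
      xlab = "SDR curve number", ylab = "element",
      main = sprintf("SDR curves - %s / %s", state$station_name,
                     state$transducer_label),
      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    )
  }
  invisible(surface)
}

#' Export the area time series
#'
#' @param state An `sdr_monitor`.
#' @param csv_path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
export_areas <- function(state, csv_path) {
  stopifnot(inherits(state, "sdr_monitor"))
  df <- data.frame(curve = seq_along(state$areas), index = state$indices,
                   area = state$areas)
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}

#' Append notifications to a JSON-lines event log
#'
#' @param notifications Data frame from [notify()].
#' @param path JSON-lines file path (one event object per line).
#' @param identity Optional named list (station, transducer) merged into each
#'   event.
#' @return `path`, invisibly.
#' @export
write_notification_log <- function(notifications, path, identity = list()) {
  con <- file(path, "a")
  on.exit(close(con))
  for (i in seq_len(nrow(notifications))) {
    event <- c(as.list(notifications[i, ]), identity)
    writeLines(jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
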