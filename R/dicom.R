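# Minimal DICOM support: explicit-VR little-endian secondary-capture-style
# files carrying exactly the metadata the selection and calibration rules
# consult (StationName, TransducerData, SequenceOfUltrasoundRegions with
# PhysicalDeltaX, StudyDate/StudyTime) plus 8-bit interleaved RGB pixel data.
# Both the fixture writer and the archive reader live here so the round trip
# is self-contained; the writer produces standard-conformant files that
# pydicom and other DICOM tooling read unchanged.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

LONG_FORM_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

dcm_string_value <- function(value, vr) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dcm_pad(charToRaw(as.character(value)), pad)
}

# Encode one data element (explicit VR little endian).
dcm_element <- function(group, element, vr, value_bytes) {
  head <- c(dcm_uint(group, 2), dcm_uint(element, 2), charToRaw(vr))
  if (vr %in% LONG_FORM_VRS) {
    c(head, as.raw(c(0, 0)), dcm_uint(length(value_bytes), 4), value_bytes)
  } else {
    if (length(value_bytes) > 65534) stop("value too long for short-form VR ", vr)
    c(head, dcm_uint(length(value_bytes), 2), value_bytes)
  }
}

dcm_str_element <- function(group, element, vr, value) {
  dcm_element(group, element, vr, dcm_string_value(value, vr))
}

# Sequence of items, each with a defined length.
dcm_sequence <- function(group, element, items) {
  body <- unlist(lapply(items, function(item_bytes) {
    c(dcm_uint(0xFFFE, 2), dcm_uint(0xE000, 2), dcm_uint(length(item_bytes), 4),
      item_bytes)
  }))
  if (is.null(body)) body <- raw(0)
  dcm_element(group, element, "SQ", body)
}

# One ultrasound region item: physical units code 3 = cm, and the physical
# pixel pitch along X in cm per pixel (the DICOM region calibration convention).
dcm_us_region_item <- function(physical_delta_x_cm) {
  c(
    dcm_element(0x0018, 0x6024, "US", dcm_uint(3, 2)),
    dcm_element(0x0018, 0x602C, "FD",
                writeBin(as.double(physical_delta_x_cm), raw(), size = 8,
                         endian = "little"))
  )
}

new_uid <- function(suffix) {
  paste0("1.2.826.0.1.3680043.8.498.", suffix)
}

#' Layout of a stored ultrasound frame
#'
#' Describes how the B-mode rectangle is embedded in the stored DICOM frame:
#' the full stored size, the position of the B-mode image inside a zero-filled
#' surround, optional logotype/text boxes of nonzero pixels, the physical
#' pixel pitch, and the number of ultrasound regions declared in the metadata
#' (more than one region marks Doppler-curve or side-by-side displays, which
#' the selection rules reject).
#'
#' @param full_rows,full_cols Stored frame size in pixels.
#' @param bmode_row,bmode_col Top-left corner (1-based) of the embedded B-mode
#'   rectangle; it must leave a zero border on all sides.
#' @param bmode_rows,bmode_cols Size of the embedded B-mode rectangle.
#' @param logotype_boxes List of `c(row, col, height, width)` rectangles filled
#'   with text-like nonzero pixels (vendor logotypes, measurement readouts).
#' @param physical_delta_x Physical pixel pitch along X, in cm per pixel
#'   (DICOM ultrasound region calibration convention).
#' @param region_count Number of ultrasound region items to declare.
#' @return An object of class `fixture_layout`.
#' @export
fixture_layout <- function(full_rows, full_cols, bmode_row, bmode_col,
                           bmode_rows, bmode_cols, logotype_boxes = list(),
                           physical_delta_x = 0.01, region_count = 1L) {
  stopifnot(
    bmode_row > 1, bmode_col > 1,
    bmode_row + bmode_rows - 1 < full_rows,
    bmode_col + bmode_cols - 1 < full_cols,
    region_count >= 1
  )
  structure(
    list(full_rows = as.integer(full_rows), full_cols = as.integer(full_cols),
         bmode_row = as.integer(bmode_row), bmode_col = as.integer(bmode_col),
         bmode_rows = as.integer(bmode_rows), bmode_cols = as.integer(bmode_cols),
         logotype_boxes = logotype_boxes,
         physical_delta_x = as.numeric(physical_delta_x),
         region_count = as.integer(region_count)),
    class = "fixture_layout"
  )
}

# Place the B-mode frame inside the zero surround and render logotype boxes
# as a deterministic text-like dot pattern.
embed_frame <- function(frame, layout) {
  stopifnot_matrix(frame, "frame")
  if (nrow(frame) != layout$bmode_rows || ncol(frame) != layout$bmode_cols) {
    stop(sprintf("frame is %d x %d but layout declares a %d x %d B-mode rectangle",
                 nrow(frame), ncol(frame), layout$bmode_rows, layout$bmode_cols))
  }
  full <- matrix(0, layout$full_rows, layout$full_cols)
  rows <- layout$bmode_row + seq_len(layout$bmode_rows) - 1L
  cols <- layout$bmode_col + seq_len(layout$bmode_cols) - 1L
  full[rows, cols] <- round(clip255(frame))
  for (box in layout$logotype_boxes) {
    br <- box[1] + seq_len(box[3]) - 1L
    bc <- box[2] + seq_len(box[4]) - 1L
    if (any(br < 1 | br > layout$full_rows | bc < 1 | bc > layout$full_cols)) {
      stop("logotype box outside the stored frame")
    }
    pattern <- outer(br, bc, function(r, c) ifelse((r + 2 * c) %% 3 == 0, 0, 220))
    full[br, bc] <- pattern
  }
  full
}

#' Write an 8-bit RGB DICOM fixture
#'
#' Embeds a grayscale B-mode frame at the layout's offset inside a zero-filled
#' surround, renders any logotype boxes, replicates the result into three RGB
#' channels and writes an explicit-VR little-endian DICOM file with the
#' metadata the selection rules consult.
#'
#' @param frame Grayscale matrix (gray levels 0-255) of the B-mode image at
#'   stored resolution.
#' @param layout A [fixture_layout()].
#' @param tags Named list with `station_name`, `transducer_label`,
#'   `study_date` (`"YYYYMMDD"`) and optionally `study_time` (`"HHMMSS"`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dicom_fixture <- function(frame, layout, tags, path) {
  stopifnot(inherits(layout, "fixture_layout"))
  required <- c("station_name", "study_date")
  missing_tags <- setdiff(required, names(tags))
  if (length(missing_tags) > 0) {
    stop("tags must include: ", paste(missing_tags, collapse = ", "))
  }
  if (is.null(tags$study_time)) tags$study_time <- "120000"
  if (is.null(tags$transducer_label)) tags$transducer_label <- ""

  full <- embed_frame(frame, layout)
  # interleaved RGB samples, row-major: channel fastest, then column, then row
  gray <- as.integer(t(full))
  pixel_bytes <- as.raw(rep(gray, each = 3L))
  if (length(pixel_bytes) %% 2 == 1) pixel_bytes <- c(pixel_bytes, as.raw(0))

  sop_instance <- new_uid(paste0(
    format(as.integer(sum(full) %% 100000)), ".",
    gsub("[^0-9]", "", paste0(tags$study_date, tags$study_time))))

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str_element(0x0002, 0x0002, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dcm_str_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_str_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    dcm_str_element(0x0002, 0x0012, "UI", new_uid("1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta), 4)), meta)

  regions <- replicate(layout$region_count,
                       dcm_us_region_item(layout$physical_delta_x),
                       simplify = FALSE)

  dataset <- c(
    dcm_str_element(0x0008, 0x0016, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dcm_str_element(0x0008, 0x0018, "UI", sop_instance),
    dcm_str_element(0x0008, 0x0020, "DA", tags$study_date),
    dcm_str_element(0x0008, 0x0030, "TM", tags$study_time),
    dcm_str_element(0x0008, 0x0060, "CS", "US"),
    dcm_str_element(0x0008, 0x1010, "SH", tags$station_name),
    dcm_str_element(0x0018, 0x5010, "LO", tags$transducer_label),
    dcm_sequence(0x0018, 0x6011, regions),
    dcm_element(0x0028, 0x0002, "US", dcm_uint(3, 2)),
    dcm_str_element(0x0028, 0x0004, "CS", "RGB"),
    dcm_element(0x0028, 0x0006, "US", dcm_uint(0, 2)),
    dcm_element(0x0028, 0x0010, "US", dcm_uint(layout$full_rows, 2)),
    dcm_element(0x0028, 0x0011, "US", dcm_uint(layout$full_cols, 2)),
    dcm_element(0x0028, 0x0100, "US", dcm_uint(8, 2)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint(8, 2)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint(7, 2)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint(0, 2)),
    dcm_element(0x7FE0, 0x0010, "OB", pixel_bytes)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reader

dcm_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}

rd_take <- function(rd, n) {
  if (rd$pos + n - 1L > length(rd$bytes)) stop("truncated DICOM stream")
  out <- rd$bytes[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + n
  out
}

rd_uint <- function(rd, size) {
  b <- as.integer(rd_take(rd, size))
  sum(b * 256^(seq_len(size) - 1))
}

# Read one element; returns list(group, element, vr, value raw vector) or a
# parsed sequence item list for SQ.
rd_element <- function(rd) {
  group <- rd_uint(rd, 2)
  element <- rd_uint(rd, 2)
  vr <- rawToChar(rd_take(rd, 2))
  if (vr %in% LONG_FORM_VRS) {
    rd_take(rd, 2)  # reserved
    len <- rd_uint(rd, 4)
  } else {
    len <- rd_uint(rd, 2)
  }
  if (len == 4294967295) {
    stop("undefined-length elements are not supported by this reader")
  }
  if (vr == "SQ") {
    items <- list()
    end <- rd$pos + len
    while (rd$pos < end) {
      ig <- rd_uint(rd, 2); ie <- rd_uint(rd, 2)
      if (ig != 0xFFFE || ie != 0xE000) stop("malformed sequence item")
      ilen <- rd_uint(rd, 4)
      if (ilen == 4294967295) stop("undefined-length items are not supported")
      sub <- dcm_reader(rd_take(rd, ilen))
      item <- list()
      while (sub$pos <= length(sub$bytes)) {
        el <- rd_element(sub)
        item[[sprintf("%04X%04X", el$group, el$element)]] <- el
      }
      items[[length(items) + 1L]] <- item
    }
    return(list(group = group, element = element, vr = vr, items = items))
  }
  list(group = group, element = element, vr = vr, value = rd_take(rd, len))
}

dcm_decode <- function(el) {
  switch(el$vr,
    US = {
      b <- as.integer(el$value)
      n <- length(b) / 2
      vapply(seq_len(n), function(i) b[2 * i - 1] + 256 * b[2 * i], numeric(1))
    },
    UL = rd_uint(dcm_reader(el$value), 4),
    FD = readBin(el$value, "double", n = length(el$value) / 8, size = 8,
                 endian = "little"),
    # string VRs: strip trailing space/NUL padding at the byte level
    {
      v <- el$value
      while (length(v) > 0 && v[length(v)] %in% as.raw(c(0x00, 0x20))) {
        v <- v[-length(v)]
      }
      rawToChar(v)
    }
  )
}

#' Read a DICOM ultrasound frame
#'
#' Parses an explicit-VR little-endian DICOM file and returns the fields the
#' selection, extraction and calibration rules consult, plus the RGB pixel
#' data. Files written by [write_dicom_fixture()] round-trip exactly.
#'
#' @param path DICOM file path.
#' @return An object of class `dicom_record` with fields `station_name`,
#'   `transducer_label`, `region_count`, `physical_delta_x` (cm per pixel,
#'   `NA` if absent), `study_date`, `study_time`, `rows`, `cols`,
#'   `pixel_data` (rows x cols x 3 array) and `path`.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM marker): ", path)
  }
  rd <- dcm_reader(bytes)
  rd$pos <- 133L
  fields <- list(path = path, station_name = NA_character_,
                 transducer_label = NA_character_, region_count = 0L,
                 physical_delta_x = NA_real_, study_date = NA_character_,
                 study_time = NA_character_, rows = NA_integer_,
                 cols = NA_integer_, samples_per_pixel = NA_integer_,
                 planar_configuration = 0L, pixel_bytes = NULL)
  while (rd$pos <= length(rd$bytes)) {
    el <- rd_element(rd)
    tag <- sprintf("%04X%04X", el$group, el$element)
    if (tag == "00186011") {
      fields$region_count <- length(el$items)
      if (length(el$items) > 0) {
        first <- el$items[[1]]
        if (!is.null(first[["0018602C"]])) {
          fields$physical_delta_x <- dcm_decode(first[["0018602C"]])[1]
        }
      }
    } else if (tag == "00081010") {
      fields$station_name <- dcm_decode(el)
    } else if (tag == "00185010") {
      fields$transducer_label <- dcm_decode(el)
    } else if (tag == "00080020") {
      fields$study_date <- dcm_decode(el)
    } else if (tag == "00080030") {
      fields$study_time <- dcm_decode(el)
    } else if (tag == "00280010") {
      fields$rows <- as.integer(dcm_decode(el)[1])
    } else if (tag == "00280011") {
      fields$cols <- as.integer(dcm_decode(el)[1])
    } else if (tag == "00280002") {
      fields$samples_per_pixel <- as.integer(dcm_decode(el)[1])
    } else if (tag == "00280006") {
      fields$planar_configuration <- as.integer(dcm_decode(el)[1])
    } else if (tag == "7FE00010") {
      fields$pixel_bytes <- el$value
    }
  }
  if (is.null(fields$pixel_bytes) || is.na(fields$rows) || is.na(fields$cols)) {
    stop("DICOM file has no usable pixel data: ", path)
  }
  npix <- fields$rows * fields$cols
  spp <- fields$samples_per_pixel
  if (is.na(spp)) spp <- 1L
  vals <- as.integer(fields$pixel_bytes[seq_len(npix * spp)])
  if (spp == 3L && fields$planar_configuration == 0L) {
    # interleaved: channel fastest, then column, then row
    arr <- aperm(array(vals, dim = c(3, fields$cols, fields$rows)), c(3, 2, 1))
  } else if (spp == 3L) {
    arr <- aperm(array(vals, dim = c(fields$cols, fields$rows, 3)), c(2, 1, 3))
  } else {
    arr <- array(rep(t(matrix(vals, fields$cols, fields$rows)), 3),
                 dim = c(fields$rows, fields$cols, 3))
  }
  fields$pixel_data <- arr
  fields$pixel_bytes <- NULL
  structure(fields, class = "dicom_record")
}

#' @export
print.dicom_record <- function(x, ...) {
  cat(sprintf("DICOM record: %s\n", basename(x$path)))
  cat(sprintf("  station '%s', transducer '%s', %d region(s)\n",
              x$station_name, x$transducer_label, x$region_count))
  cat(sprintf("  %d x %d px, delta_x = %s cm/px, study %s %s\n",
              x$rows, x$cols, format(x$physical_delta_x), x$study_date,
              x$study_time))
  invisible(x)
}

#' Read all DICOM files in a directory or file list
#'
#' Unreadable files are skipped with a warning so that a messy archive does
#' not halt monitoring.
#'
#' @param paths A directory (scanned non-recursively for files) or an explicit
#'   character vector of file paths.
#' @return List of `dicom_record` objects.
#' @export
read_dicom_dir <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
    paths <- paths[!dir.exists(paths)]
  }
  records <- list()
  for (p in paths) {
    rec <- tryCatch(read_dicom(p), error = function(e) {
      warning(sprintf("skipping %s: %s", p, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records
}
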