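make_layout <- function(region_count = 1L, logotype_boxes = list()) {
  fixture_layout(full_rows = 120L, full_cols = 160L,
                 bmode_row = 21L, bmode_col = 31L,
                 bmode_rows = 60L, bmode_cols = 100L,
                 logotype_boxes = logotype_boxes,
                 physical_delta_x = 0.05, region_count = region_count)
}

test_that("DICOM fixtures round-trip tags, geometry and pixels", {
  frame <- matrix(round(seq(0, 255, length.out = 6000)), 60, 100)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(frame, make_layout(),
                      tags = list(station_name = "USX",
                                  transducer_label = "L12-5",
                                  study_date = "20231224",
                                  study_time = "101530"),
                      path = path)
  rec <- read_dicom(path)
  expect_equal(rec$station_name, "USX")
  expect_equal(rec$transducer_label, "L12-5")
  expect_equal(rec$region_count, 1L)
  expect_equal(rec$physical_delta_x, 0.05)
  expect_equal(rec$study_date, "20231224")
  expect_equal(rec$study_time, "101530")
  expect_equal(dim(rec$pixel_data), c(120L, 160L, 3L))
  # all three channels carry the embedded gray frame; the surround is zero
  embedded <- rec$pixel_data[21:80, 31:130, 1]
  expect_equal(embedded, frame)
  expect_identical(rec$pixel_data[, , 1], rec$pixel_data[, , 2])
  surround <- rec$pixel_data[1:20, , ]
  expect_true(all(surround == 0))
})

test_that("declared region count round-trips (Doppler/side-by-side marker)", {
  frame <- matrix(100, 60, 100)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(frame, make_layout(region_count = 2L),
                      tags = list(station_name = "USX", study_date = "20240101"),
                      path = path)
  expect_equal(read_dicom(path)$region_count, 2L)
})

test_that("pydicom reads fixtures identically (independent DICOM oracle)", {
  frame <- matrix(rep(c(10, 200), 3000), 60, 100)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(frame, make_layout(),
                      tags = list(station_name = "ORACLE",
                                  transducer_label = "ML 6-15",
                                  study_date = "20240315"),
                      path = path)
  script <- paste(
    "import pydicom, sys",
    sprintf("ds = pydicom.dcmread(r'%s')", path),
    "print(ds.StationName)",
    "print(ds.TransducerData)",
    "print(len(ds.SequenceOfUltrasoundRegions))",
    "print(ds.SequenceOfUltrasoundRegions[0].PhysicalDeltaX)",
    "print(ds.pixel_array.shape)",
    "print(int(ds.pixel_array.sum()))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    fail(paste("pydicom oracle failed:", paste(out, collapse = " | ")))
  }
  expect_equal(out[1], "ORACLE")
  expect_equal(out[2], "ML 6-15")
  expect_equal(out[3], "1")
  expect_equal(as.numeric(out[4]), 0.05)
  expect_equal(out[5], "(120, 160, 3)")
  expect_equal(as.numeric(out[6]), 3 * sum(matrix(round(frame), 60, 100)))
})

test_that("unwritable paths and malformed files raise errors", {
  frame <- matrix(0, 60, 100)
  expect_error(suppressWarnings(
    write_dicom_fixture(frame, make_layout(),
                        tags = list(station_name = "A",
                                    study_date = "20240101"),
                        path = file.path(tempdir(), "no", "such",
                                         "dir", "x.dcm"))))
  bad <- withr::local_tempfile(fileext = ".dcm")
  writeBin(raw(200), bad)
  expect_error(read_dicom(bad), "DICM")
})

test_that("read_dicom_dir skips unreadable files with a warning", {
  dir <- withr::local_tempdir()
  frame <- matrix(50, 60, 100)
  write_dicom_fixture(frame, make_layout(),
                      tags = list(station_name = "A", study_date = "20240101"),
                      path = file.path(dir, "ok.dcm"))
  writeLines("not dicom", file.path(dir, "junk.dcm"))
  expect_warning(records <- read_dicom_dir(dir), "skipping")
  expect_length(records, 1)
  expect_equal(records[[1]]$station_name, "A")
})
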