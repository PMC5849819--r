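test_that("a single nonzero rectangle yields exactly its corners", {
  img <- matrix(0, 600, 900)
  img[101:500, 201:800] <- 80
  reg <- find_bmode_region(img)
  expect_equal(reg$corners, list(top = 101L, bottom = 500L,
                                 left = 201L, right = 800L))
  expect_equal(reg$area, 400L * 600L)
})

test_that("the largest of two components wins and the rest is zeroed", {
  img <- matrix(0, 100, 100)
  img[10:49, 10:34] <- 50   # area 1000
  img[70:79, 70:74] <- 200  # area 50
  reg <- find_bmode_region(img)
  expect_equal(reg$corners, list(top = 10L, bottom = 49L,
                                 left = 10L, right = 34L))
  expect_true(all(reg$cleaned[70:79, 70:74] == 0))
  expect_true(all(reg$cleaned[10:49, 10:34] == 50))
})

test_that("component labeling matches a brute-force 8-connectivity oracle", {
  set.seed(404)
  for (trial in 1:25) {
    mask <- matrix(runif(30 * 40) < 0.35, 30, 40)
    if (!any(mask)) next
    img <- matrix(0, 30, 40)
    img[mask] <- 100
    reg <- find_bmode_region(img)
    lab <- oracle_label8(mask)
    sizes <- table(lab[lab > 0])
    best <- as.integer(names(sizes)[which.max(sizes)])
    expect_equal(reg$area, as.integer(max(sizes)))
    expect_equal(reg$cleaned > 0, lab == best)
  }
})

test_that("trapezoidal regions are extracted at the width of the top edge", {
  img <- matrix(0, 200, 1000)
  # region narrowing with depth: top edge spans columns 300-699
  for (r in 1:150) {
    shrink <- floor((r - 1) / 2)
    img[r + 20, (300 + shrink):(699 - shrink)] <- 90
  }
  reg <- find_bmode_region(img)
  expect_equal(reg$corners$left, 300L)
  expect_equal(reg$corners$right, 699L)
  expect_equal(reg$corners$top, 21L)
  expect_equal(reg$corners$bottom, 170L)
})

test_that("all-zero images raise a no-region error", {
  expect_error(find_bmode_region(matrix(0, 10, 10)), "no B-mode region")
})

test_that("lateral zoom check applies the closed accepted interval in mm", {
  pr <- transducer_profile("ML 6-15")
  corners_for <- function(px) list(top = 1L, bottom = 100L,
                                   left = 1L, right = as.integer(px))
  # 500 columns at 0.01 cm/px -> 50.0 mm
  expect_true(check_lateral_zoom(corners_for(500), 0.01, pr)$accept)
  # 480 columns -> 48.0 mm, under
  z <- check_lateral_zoom(corners_for(480), 0.01, pr)
  expect_false(z$accept)
  expect_equal(z$reason, "width_under")
  # closed upper boundary: 515 columns -> exactly 51.5 mm
  z <- check_lateral_zoom(corners_for(515), 0.01, pr)
  expect_true(z$accept)
  expect_equal(z$physical_width_mm, 51.5)
  # just above
  expect_equal(check_lateral_zoom(corners_for(516), 0.01, pr)$reason,
               "width_over")
  # no calibration
  expect_equal(check_lateral_zoom(corners_for(500), NA, pr)$reason,
               "no_calibration")
})

test_that("resizing hits the shipped profile geometries exactly", {
  src <- matrix(runif(400 * 600, 0, 255), 400, 600)
  ml <- resize_bmode(src, transducer_profile("ML 6-15"))
  expect_equal(dim(ml), c(500L, 336L))
  l12 <- resize_bmode(src, transducer_profile("L12-5"))
  expect_equal(dim(l12), c(500L, 256L))
})

test_that("bicubic resize preserves constants and rejects degenerate input", {
  const <- matrix(42, 37, 53)
  out <- resize_bicubic(const, 500, 336)
  expect_equal(out, matrix(42, 500, 336))
  expect_error(resize_bicubic(matrix(1, 1, 10), 5, 5), "degenerate")
})

test_that("resize maps lateral positions covariantly", {
  # dark column at fractional position p of the stored width should land
  # within +/-2 columns of round(p * element_count)
  pr <- transducer_profile("ML 6-15")
  for (col in c(100, 250, 400)) {
    src <- matrix(200, 300, 500)
    src[, col] <- 0
    out <- resize_bmode(src, pr)
    expected <- round((col - 0.5) / 500 * 336)
    expect_lte(abs(which.min(colMeans(out)) - expected), 2)
  }
})

test_that("extraction round-trips synthetic fixture layouts exactly", {
  lay <- fixture_layout(full_rows = 300L, full_cols = 700L,
                        bmode_row = 41L, bmode_col = 101L,
                        bmode_rows = 200L, bmode_cols = 500L,
                        physical_delta_x = 0.01)
  bg <- background_model(mean_level = 120, speckle_sigma = 0.1, seed = 31)
  frame <- generate_frame(bg, list(), 1, nrow = 200, ncol = 500) + 1
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(frame, lay,
                      tags = list(station_name = "S", study_date = "20240101"),
                      path = path)
  rec <- read_dicom(path)
  gray <- to_grayscale(rec$pixel_data)
  reg <- find_bmode_region(gray)
  expect_equal(reg$corners, list(top = 41L, bottom = 240L,
                                 left = 101L, right = 600L))
  ext <- extract_bmode(gray, rec$physical_delta_x, transducer_profile("ML 6-15"))
  expect_equal(ext$status, "accepted")
  expect_equal(ext$extract$physical_width_mm, 50)
})

test_that("every input yields exactly one of accepted / enumerated rejection", {
  pr <- transducer_profile("ML 6-15")
  zero <- matrix(0, 50, 50)
  expect_equal(extract_bmode(zero, 0.01, pr)$reason, "no_region")
  img <- matrix(0, 300, 700)
  img[41:240, 101:600] <- 90
  expect_equal(extract_bmode(img, NA, pr)$reason, "no_calibration")
  expect_equal(extract_bmode(img, 0.02, pr)$reason, "width_over")
  expect_equal(extract_bmode(img, 0.005, pr)$reason, "width_under")
  expect_equal(extract_bmode(img, 0.01, pr)$status, "accepted")
})
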