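# Shared fixtures built in code at test time.

# Small transducer for fast property tests; acceptance checks use the
# shipped full-size profiles.
test_profile <- function(elements = 64L, height = 60L) {
  transducer_profile("TEST", element_count = elements, resized_height = height)
}

# Parameters scaled down for small stacks while keeping the default
# thresholds and band.
test_params <- function(n_stack = 30L, n_select = 7L, n_rep = 20L, seed = 1L,
                        ...) {
  sdr_params(n_stack = n_stack, n_select = n_select, n_rep = n_rep,
             seed = seed, ...)
}

# A stack of constant frames (value `level`) of the given geometry.
uniform_stack <- function(n, profile, level = 100) {
  image_stack(replicate(n, matrix(level, profile$resized_height,
                                  profile$element_count), simplify = FALSE))
}

# In-memory dicom_record without touching disk.
fake_record <- function(station = "US1", transducer = "ML 6-15",
                        region_count = 1L, cols = 960L, rows = 720L,
                        study_date = "20240101", study_time = "090000",
                        path = "mem.dcm") {
  structure(
    list(path = path, station_name = station, transducer_label = transducer,
         region_count = as.integer(region_count),
         physical_delta_x = 0.01, study_date = study_date,
         study_time = study_time, rows = as.integer(rows),
         cols = as.integer(cols), samples_per_pixel = 3L,
         planar_configuration = 0L,
         pixel_data = array(0, dim = c(2, 2, 3))),
    class = "dicom_record"
  )
}
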