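test_that("text grids parse with exact values and top-left origin", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("33.0,34.0,33.5", "33.2,34.1,33.6"), p)
  fr <- read_temperature_grid(p)
  expect_equal(fr$height, 2L)
  expect_equal(fr$width, 3L)
  expect_equal(fr$temps, matrix(c(33.0, 34.0, 33.5, 33.2, 34.1, 33.6),
                                2, byrow = TRUE))
  expect_equal(fr$emissivity, 0.98)  # default when no sidecar

  # alternative dialects: semicolon + decimal comma, and tab
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("33,0;34,0", "33,2;34,1"), p2)
  fr2 <- read_temperature_grid(p2, delim = ";", dec = ",")
  expect_equal(fr2$temps, matrix(c(33.0, 34.0, 33.2, 34.1), 2, byrow = TRUE))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("33.5\t34.5", p3)
  expect_equal(read_temperature_grid(p3, delim = "\t")$temps,
               matrix(c(33.5, 34.5), 1))
})

test_that("format errors name the offending row and token", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("33.0,34.0,33.5", "33.2,34.1"), p)
  err <- expect_error(read_temperature_grid(p), class = "ht_format_error")
  expect_match(conditionMessage(err), "row 2")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("33.0,oops", "33.2,34.1"), p2)
  err2 <- expect_error(read_temperature_grid(p2), class = "ht_format_error")
  expect_match(conditionMessage(err2), "'oops' at row 1, column 2")
})

test_that("out-of-band temperatures are rejected with their coordinates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("33.0,90.0", "33.2,34.1"), p)
  err <- expect_error(read_temperature_grid(p), class = "ht_validation_error")
  expect_match(conditionMessage(err), "90")
  # masked (NA) pixels are allowed where out-of-band values are not
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("33.0,NA", "33.2,34.1"), p2)
  expect_true(is.na(read_temperature_grid(p2)$temps[1, 2]))
  # a wider band admits the same value
  expect_error(thermal_frame(matrix(90)), class = "ht_validation_error")
  expect_silent(thermal_frame(matrix(90), band = c(15, 95)))
})

test_that("write/read round-trip is the identity, including metadata sidecar", {
  fr <- thermal_frame(matrix(c(33.123456789012345, 34, 33.5, 36), 2),
                      emissivity = 0.95, subject_id = "p1",
                      capture_time = "2021-06-01T10:00:00")
  p <- withr::local_tempfile(fileext = ".csv")
  write_temperature_grid(fr, p)
  back <- read_temperature_grid(p)
  expect_identical(back$temps, fr$temps)
  expect_equal(back$emissivity, 0.95)
  expect_equal(back$subject_id, "p1")
  expect_equal(back$capture_time, "2021-06-01T10:00:00")

  # degenerate 1x1 frame writes a single-line file
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_temperature_grid(thermal_frame(matrix(34.0)), p1)
  expect_equal(readLines(p1), "34")
  expect_equal(read_temperature_grid(p1)$temps, matrix(34.0))
})

test_that("round-trip property holds on 200 random frames", {
  withr::local_seed(41)
  p <- withr::local_tempfile(fileext = ".csv")
  for (i in 1:200) {
    fr <- random_valid_frame()
    if (i %% 3 == 0) fr$temps[sample(length(fr$temps), 1)] <- NA  # invalid px
    write_temperature_grid(fr, p, sidecar = FALSE)
    back <- read_temperature_grid(p)
    expect_identical(dim(back$temps), dim(fr$temps))
    expect_true(all(abs(back$temps - fr$temps) <= 0.001, na.rm = TRUE))
    expect_identical(is.na(back$temps), is.na(fr$temps))
  }
})

test_that("radiometric affine conversion follows gain * DN + offset", {
  cal <- radiometric_calibration(gain = 0.01, offset = 20)
  p <- withr::local_tempfile(fileext = ".tif")
  dn <- matrix(c(1500L, 1600L, 1700L, 1800L), 2)
  tiff::writeTIFF(dn / 65535, p, bits.per.sample = 16L)
  fr <- read_radiometric_image(p, cal)
  expect_equal(fr$temps, 0.01 * dn + 20)
  expect_equal(fr$temps[1, 1], 35.0)
})

test_that("sentinel DN pixels are masked and excluded from statistics", {
  cal <- radiometric_calibration(0.01, 20, invalid_value = 0L)
  p <- withr::local_tempfile(fileext = ".tif")
  dn <- matrix(c(1500L, 0L, 1700L, 1800L), 2)
  tiff::writeTIFF(dn / 65535, p, bits.per.sample = 16L)
  fr <- read_radiometric_image(p, cal)
  expect_true(is.na(fr$temps[2, 1]))
  expect_equal(max(fr$temps, na.rm = TRUE), 38.0)
  expect_equal(mean(fr$temps, na.rm = TRUE), mean(c(35, 37, 38)))
})

test_that("radiometric preconditions and format errors are enforced", {
  expect_error(radiometric_calibration(gain = 0), class = "ht_precondition_error")
  # multi-channel raster rejected
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), p)
  expect_error(read_radiometric_image(p, radiometric_calibration(0.01, 20)),
               class = "ht_format_error")
  # all temperatures out of band
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(c(100L, 200L), 1) / 65535, p2, bits.per.sample = 16L)
  expect_error(read_radiometric_image(p2, radiometric_calibration(0.01, 90)),
               class = "ht_validation_error")
})

test_that("affine conversion preserves DN order over the full 16-bit ramp", {
  ramp <- matrix(0:65535, 256, 256)
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(ramp / 65535, p, bits.per.sample = 16L)
  fr <- read_radiometric_image(p, radiometric_calibration(1e-4, 20),
                               band = c(15, 45))
  v <- as.vector(fr$temps)
  expect_equal(v, 1e-4 * 0:65535 + 20)
  expect_true(all(diff(v) > 0))
})

test_that("validation rejects frames with unmasked out-of-band values (fuzz)", {
  withr::local_seed(42)
  for (i in 1:50) {
    temps <- matrix(runif(30, 28, 40), 5)
    bad <- sample(30, 1)
    temps[bad] <- sample(c(runif(1, -10, 14.9), runif(1, 45.1, 200)), 1)
    expect_error(thermal_frame(temps), class = "ht_validation_error")
    temps[bad] <- NA
    expect_silent(thermal_frame(temps))
  }
})
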