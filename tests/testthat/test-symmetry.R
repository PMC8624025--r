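tm <- function(v, kind = "differential") temperature_matrix(v, kind)

test_that("ROI extraction copies the requested block", {
  # full-resolution frontal frame with the published ROI size
  frame <- thermal_frame(matrix(33 + sin(seq_len(768 * 1024)) %% 2, 768, 1024))
  roi <- roi_spec(top = 100, left = 200, height = 350, width = 250)
  M <- extract_roi(frame, roi, "healthy")
  expect_equal(dim(M), c(350L, 250L))
  expect_equal(M[1, 1], frame$temps[101, 201])
  expect_equal(M[350, 250], frame$temps[450, 450])

  # whole-frame ROI is the identity extraction
  small <- thermal_frame(matrix(runif(12, 30, 36), 3))
  whole <- extract_roi(small, roi_spec(0, 0, 3, 4))
  expect_equal(unclass(whole)[seq_len(12)], small$temps[seq_len(12)])

  # off-by-one overhang
  expect_error(extract_roi(small, roi_spec(1, 0, 3, 4)),
               class = "ht_bounds_error")
  expect_error(roi_spec(0, 0, 0, 4), class = "ht_precondition_error")
})

test_that("mirroring reverses columns and is an involution", {
  M <- temperature_matrix(matrix(1:6, 2, byrow = TRUE) + 30, "healthy")
  Ms <- mirror_matrix(M)
  expect_equal(matrix_kind(Ms), "mirrored_healthy")
  expect_equal(unclass(Ms)[1, ], c(33, 32, 31))
  expect_equal(unclass(Ms)[2, ], c(36, 35, 34))
  # single column is a fixed point
  one <- temperature_matrix(matrix(c(31, 32), 2, 1), "healthy")
  expect_equal(unclass(mirror_matrix(one))[, 1], c(31, 32))

  withr::local_seed(7)
  for (i in 1:200) {
    m <- sample(1:64, 1); n <- sample(1:64, 1)
    A <- temperature_matrix(matrix(runif(m * n, 28, 40), m, n), "healthy")
    back <- mirror_matrix(mirror_matrix(A))
    expect_identical(unclass(back)[seq_along(A)], unclass(A)[seq_along(A)])
    expect_equal(matrix_kind(back), "healthy")
  }
})

test_that("differential map subtracts the mirrored healthy matrix", {
  D <- tm(matrix(c(37.2, 33.0), 1), "diseased")
  H <- tm(matrix(c(33.0, 34.0), 1), "healthy")
  R <- differential_map(D, H)
  expect_equal(matrix_kind(R), "differential")
  expect_equal(unclass(R)[1, ], c(3.2, 0.0))

  # perfect contralateral symmetry gives an identically zero map
  withr::local_seed(11)
  Hv <- matrix(runif(20, 30, 36), 4)
  Dv <- Hv[, 5:1]
  R0 <- differential_map(tm(Dv, "diseased"), tm(Hv, "healthy"))
  expect_true(all(unclass(R0) == 0))

  # invalid pixels propagate; others unaffected
  Dna <- Dv; Dna[2, 3] <- NA
  Rna <- differential_map(tm(Dna, "diseased"), tm(Hv, "healthy"))
  expect_true(is.na(Rna[2, 3]))
  expect_equal(sum(is.na(Rna)), 1L)
  expect_true(all(unclass(Rna)[-which(is.na(Rna))] == 0))

  expect_error(differential_map(tm(matrix(33, 1, 2), "diseased"),
                                tm(matrix(33, 2, 2), "healthy")),
               class = "ht_dimension_error")
})

test_that("differential map is linear in a constant offset of the diseased side", {
  withr::local_seed(13)
  for (i in 1:200) {
    m <- sample(1:20, 1); n <- sample(1:20, 1)
    Hv <- matrix(runif(m * n, 29, 38), m, n)
    Dv <- matrix(runif(m * n, 29, 38), m, n)
    cc <- runif(1, -2, 2)
    base <- differential_map(tm(Dv, "diseased"), tm(Hv, "healthy"))
    shifted <- differential_map(tm(Dv + cc, "diseased"), tm(Hv, "healthy"))
    expect_equal(unclass(shifted), unclass(base) + cc, tolerance = 1e-12)
  }
})

test_that("thresholding zeroes strictly-below-cut-off values only", {
  R <- tm(matrix(c(3.2, 0.0, 2.9, -1.0), 2, byrow = TRUE))
  Rp <- threshold_map(R, 3)
  expect_equal(unclass(Rp), matrix(c(3.2, 0, 0, 0), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # a value exactly at the cut-off survives
  Re <- tm(matrix(c(3.0, 2.999999), 1))
  expect_equal(unclass(threshold_map(Re, 3))[1, ], c(3.0, 0))
  # cut-off above the maximum zeroes everything
  expect_true(all(unclass(threshold_map(R, 99)) == 0))
  expect_error(threshold_map(R, 0), class = "ht_precondition_error")
  expect_error(threshold_map(R, -1), class = "ht_precondition_error")
})

test_that("no thresholded value lies in (0, delta_t) and survivors are monotone", {
  withr::local_seed(17)
  for (i in 1:200) {
    m <- sample(1:30, 1); n <- sample(1:30, 1)
    R <- tm(matrix(rnorm(m * n, 1, 2), m, n))
    dt <- runif(1, 0.1, 4)
    v <- unclass(threshold_map(R, dt))
    expect_false(any(v > 0 & v < dt))
    # nonzero count is non-increasing in the cut-off
    counts <- vapply(c(0.5, 1, 2, 3, 4),
                     function(t) sum(unclass(threshold_map(R, t)) > 0),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("hemiface split takes mirrored offsets about the axis", {
  temps <- matrix(rep(30 + 1:10, each = 4), 4, 10)  # column j has value 30+j
  frame <- thermal_frame(temps)
  sp <- split_hemifaces(frame, axis_col = 5, roi_height = 4, roi_width = 3)
  # left ROI covers columns [2,5), right ROI [5,8) (0-based half-open)
  expect_equal(unclass(sp$diseased)[1, ], c(33, 34, 35))
  expect_equal(unclass(sp$healthy)[1, ], c(36, 37, 38))
  expect_equal(sp$diseased_roi$left, 2L)
  expect_equal(sp$healthy_roi$left, 5L)
  expect_error(split_hemifaces(frame, 1, 4, 3), class = "ht_bounds_error")

  # a mirror-symmetric frame differences to zero through the split
  half <- matrix(runif(20, 30, 36), 4, 5)
  sym <- thermal_frame(cbind(half, half[, 5:1]))
  sp2 <- split_hemifaces(sym, axis_col = 5, roi_height = 4, roi_width = 5)
  expect_true(all(unclass(differential_map(sp2$diseased, sp2$healthy)) == 0))
})

test_that("two-profile mode and single-frame split mode agree", {
  # abut two profile hemifaces into one frontal frame; analysing either way
  # must give the same differential map
  withr::local_seed(23)
  pair <- generate_baseline(phantom_spec(height = 40, width = 30, seed = 23))
  # both phantom hemifaces are already in frontal orientation, so the
  # frontal frame is their direct abutment
  frontal <- thermal_frame(cbind(pair$left$temps, pair$right$temps))
  sp <- split_hemifaces(frontal, axis_col = 30, roi_height = 40, roi_width = 30)
  R_split <- differential_map(sp$diseased, sp$healthy)

  D2 <- extract_roi(pair$left, roi_spec(0, 0, 40, 30), "diseased")
  H2 <- extract_roi(pair$right, roi_spec(0, 0, 40, 30), "healthy")
  R_two <- differential_map(D2, H2)
  expect_equal(unclass(R_split), unclass(R_two))
})

test_that("asymmetry summary counts suprathreshold pixels", {
  R <- tm(matrix(c(3.2, 0, 0, 0), 2, byrow = TRUE))
  s <- asymmetry_summary(R, thresholds = c(2, 3))
  expect_equal(s$max_delta_t, 3.2)
  expect_equal(s$at_or_above$count, c(1L, 1L))
  expect_equal(s$mean_delta_t, 0.8)

  s0 <- asymmetry_summary(tm(matrix(0, 3, 3)))
  expect_equal(s0$max_delta_t, 0)
  expect_equal(s0$at_or_above$count, c(0L, 0L))

  expect_error(asymmetry_summary(tm(matrix(NA_real_, 2, 2))),
               class = "ht_empty_error")
})

test_that("summary max equals a direct scan of a seeded 50x50 phantom differential", {
  # gaussian focus, no contralateral asymmetry: the detected maximum sits at
  # the focus centre and deviates from the amplitude only by sensor noise
  spec <- phantom_spec(height = 50, width = 50, asymmetry_sigma = 0,
                       texture_scale = 8, seed = 301)
  hs <- hotspot_spec(center = c(25, 25), semi_axes = c(12, 8),
                     amplitude = 3.5, profile = "gaussian")
  case <- generate_case(spec, hs, grade = "severe")
  D <- temperature_matrix(case$diseased_frame$temps, "diseased")
  H <- temperature_matrix(case$healthy_frame$temps, "healthy")
  R <- differential_map(D, H)
  s <- asymmetry_summary(R)
  # oracle: direct scan of the generated array
  expect_identical(s$max_delta_t, max(unclass(R)))
  sig <- 3 * spec$noise_sigma * sqrt(2)
  expect_gt(s$max_delta_t, 3.5 - sig)
  expect_lt(s$max_delta_t, 3.5 + sig)
})
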