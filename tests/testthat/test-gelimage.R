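test_that("a uniform field inverts to zero signal with the default white reference", {
  f <- write_temp_png(matrix(0.5, 32, 32))
  img <- load_gel_image(f)
  expect_s3_class(img, "gel_image")
  expect_equal(max(img$signal), 0)
  expect_equal(img$bit_depth, 8L)
  expect_false(any(img$saturated_mask))
})

test_that("a dark rectangle on a white field gives positive signal exactly inside it", {
  lum <- matrix(1, 48, 40)
  lum[10:20, 5:15] <- 0.25
  img <- load_gel_image(write_temp_png(lum))
  inside <- matrix(FALSE, 48, 40)
  inside[10:20, 5:15] <- TRUE
  expect_true(all(img$signal[inside] > 0))
  expect_true(all(img$signal[!inside] == 0))
  # the white field is at full-scale code value
  expect_true(all(img$saturated_mask[!inside]))
})

test_that("inversion is an involution where unclipped", {
  lum <- matrix(seq(0.2, 0.9, length.out = 30 * 30), 30, 30)
  f <- write_temp_png(lum)
  img <- load_gel_image(f, white_reference = 255)
  code <- round(lum * 255)
  recovered <- 255 - img$signal
  expect_equal(recovered, code, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("16-bit synthetic gel round-trips band integrals within 0.5%", {
  sp <- make_calibration_gel(noise_sd = 0, seed = 5)
  f <- tempfile(fileext = ".tif")
  r <- render_gel(sp, path = f)
  img <- load_gel_image(f)
  expect_equal(img$bit_depth, 16L)
  for (id in 1:5) {
    d <- lane_profile(img, sp$lanes[id, ])
    truth <- r$truth$integrated_signal[r$truth$lane_id == id]
    expect_equal(sum(d$values), truth, tolerance = 0.005)
  }
})

test_that("unreadable and degenerate images are refused with informative errors", {
  expect_error(load_gel_image("no/such/file.png"), "no/such/file.png")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_gel_image(bad), bad)
  expect_error(load_gel_image(write_temp_png(matrix(0.5, 8, 8))),
               "degenerate")
})

test_that("optical-density mode gives log-scaled signal", {
  lum <- matrix(1, 32, 32)
  lum[16, 16] <- 0.1
  img <- load_gel_image(write_temp_png(lum), white_reference = 255,
                        mode = "od")
  expect_equal(img$signal[16, 16], log10(255 / round(0.1 * 255)))
  expect_equal(img$signal[1, 1], 0)
})

test_that("flattening removes a pure linear gradient to under 1% of its range", {
  n <- 200
  for (rng in c(2000, -2000)) {
    grad <- matrix(rep(seq(3000, 3000 + rng, length.out = n), 40), n, 40)
    img <- gel_image(grad, bit_depth = 16L)
    out <- flatten_background(img, window_rows = 51)
    expect_lt(max(out$signal), 0.01 * abs(rng))
  }
})

test_that("flattening a zero image returns a zero image", {
  img <- gel_image(matrix(0, 64, 20))
  out <- flatten_background(img, window_rows = 17)
  expect_equal(max(out$signal), 0)
})

test_that("band integrals survive flattening a gradient-lit gel within 2%", {
  sp <- make_calibration_gel(noise_sd = 0, seed = 2)
  sp$background <- c(0.8, -0.06, 0.03)
  r <- render_gel(sp)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(r$luminance, f, bits.per.sample = 16L)
  # the brightest background corner as white reference: the modal default
  # would clip background regions brighter than the mode under a strong
  # illumination gradient
  img <- load_gel_image(f, white_reference = 0.83 * (2^16 - 1))
  img <- flatten_background(img)
  for (id in 1:5) {
    d <- lane_profile(img, sp$lanes[id, ])
    ctr <- round(r$truth$center_row[r$truth$lane_id == id])
    win <- (ctr - 30L):(ctr + 30L)
    flank <- c((ctr - 60L):(ctr - 35L), (ctr + 35L):(ctr + 60L))
    got <- sum(d$values[win]) - mean(d$values[flank]) * length(win)
    truth <- r$truth$integrated_signal[r$truth$lane_id == id]
    expect_equal(got, truth, tolerance = 0.02)
  }
})

test_that("flatten_background rejects out-of-range windows", {
  img <- gel_image(matrix(1, 50, 20))
  expect_error(flatten_background(img, window_rows = 2), "window_rows")
  expect_error(flatten_background(img, window_rows = 50), "window_rows")
})

test_that("lanes of a synthetic gel are found disjoint, sorted, one per planted lane", {
  sp <- make_degradation_gel(retained_fractions = c(0.9, 0.7, 0.5, 0.3),
                             snr = Inf, seed = 1)
  r <- render_gel(sp)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(r$luminance, f, bits.per.sample = 16L)
  img <- flatten_background(load_gel_image(f))
  lanes <- detect_lanes(img)
  expect_equal(nrow(lanes), nrow(sp$lanes))
  expect_equal(lanes$lane_id, seq_len(nrow(lanes)))
  # sorted and pairwise disjoint
  expect_true(all(diff(lanes$col_start) > 0))
  expect_true(all(lanes$col_end[-nrow(lanes)] <= lanes$col_start[-1]))
  # each detected lane sits within its planted span and contains its centre
  for (i in seq_len(nrow(lanes))) {
    expect_gte(lanes$col_start[i], sp$lanes$col_start[i])
    expect_lte(lanes$col_end[i], sp$lanes$col_end[i])
    mid <- (sp$lanes$col_start[i] + sp$lanes$col_end[i]) / 2
    expect_true(lanes$col_start[i] <= mid && mid < lanes$col_end[i])
  }
})

test_that("a blank gel raises a detection error", {
  img <- gel_image(matrix(0, 64, 64))
  expect_error(detect_lanes(img), "blank")
})

test_that("expected_n mismatches are reported with both counts", {
  sp <- make_degradation_gel(retained_fractions = c(0.9, 0.7), snr = Inf)
  r <- render_gel(sp)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(r$luminance, f, bits.per.sample = 16L)
  img <- flatten_background(load_gel_image(f))
  expect_equal(nrow(detect_lanes(img, expected_n = 3)), 3L)
  expect_error(detect_lanes(img, expected_n = 10), "3.*10|10.*3")
})

test_that("a ten-lane gel with expected_n = 10 yields ten regions", {
  sp <- make_degradation_gel(retained_fractions = rep(c(0.9, 0.6, 0.4), 3),
                             snr = Inf, seed = 4)
  r <- render_gel(sp)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(r$luminance, f, bits.per.sample = 16L)
  img <- flatten_background(load_gel_image(f))
  expect_equal(nrow(detect_lanes(img, expected_n = 10)), 10L)
})

test_that("lane profiles are column means with the documented invariances", {
  img <- gel_image(matrix(3.5, 60, 30))
  d <- lane_profile(img, lane_region(1, 5, 15))
  expect_equal(d$values, rep(3.5, 60))
  expect_false(d$baseline_subtracted)

  # a Gaussian band spanning the whole lane: profile max = amplitude
  A <- 120
  band <- matrix(rep(gauss_profile(80, 40, 5, A), 20), 80, 20)
  db <- lane_profile(gel_image(band), lane_region(1, 1, 21))
  expect_equal(max(db$values), A, tolerance = 1e-6)

  # doubling lane width over a laterally uniform band leaves it unchanged
  dn <- lane_profile(gel_image(band), lane_region(1, 5, 10))
  dw <- lane_profile(gel_image(band), lane_region(1, 3, 13))
  expect_equal(dn$values, dw$values)

  # linearity in the image
  d3 <- lane_profile(gel_image(3 * band), lane_region(1, 1, 21))
  expect_equal(d3$values, 3 * db$values)

  expect_error(lane_profile(img, lane_region(1, 25, 40)), "bounds")
})
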