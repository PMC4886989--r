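test_that("binarize is inclusive and matches element-wise comparison", {
  zero <- make_cal_frame(list(matrix(0L, 8, 8)))
  expect_false(any(binarize(zero, 50)[[1]]))
  one <- make_cal_frame(list(matrix(c(50L, 49L, rep(0L, 62)), 8, 8)))
  m <- binarize(one, 50)[[1]]
  expect_identical(sum(m), 1L)
  expect_true(m[1, 1])
  set.seed(11)
  rnd <- matrix(sample.int(200, 400, replace = TRUE) - 100L, 20, 20)
  expect_identical(binarize(make_cal_frame(list(rnd)), 30)[[1]], rnd >= 30)
})

test_that("connectivity semantics: diagonal touch", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_identical(attr(connected_components(m, 8L), "n_components"), 1L)
  expect_identical(attr(connected_components(m, 4L), "n_components"), 2L)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(attr(connected_components(empty, 8L), "n_components"), 0L)
})

test_that("connected components equal the flood-fill oracle", {
  # exhaustive over all 3x3 masks
  for (bits in 0:511) {
    m <- matrix(bitwAnd(bitwShiftR(bits, 0:8), 1L) == 1L, 3, 3)
    for (conn in c(4L, 8L)) {
      got <- connected_components(m, conn)
      want <- flood_fill_label(m, conn)
      expect_identical(canonical_partition(got), canonical_partition(want))
    }
  }
  # 100 random sparse panels
  set.seed(13)
  for (k in 1:100) {
    m <- matrix(runif(24 * 16) < 0.15, 24, 16)
    conn <- if (k %% 2) 8L else 4L
    got <- connected_components(m, conn)
    want <- flood_fill_label(m, conn)
    expect_identical(canonical_partition(got), canonical_partition(want))
    expect_identical(attr(got, "n_components"), max(want))
  }
})

test_that("score: zero background uses the noise floor", {
  panel <- matrix(0L, 21, 21)
  panel[10:12, 10:12] <- 100L   # 9-pixel spot of value 100
  sl <- find_spots(make_cal_frame(list(panel)),
                   spot_find_params(min_snr = 0))
  expect_identical(nrow(sl$spots), 1L)
  s <- sl$spots[1, ]
  expect_identical(s$area, 9L)
  expect_equal(s$snr, 100)              # (peak - 0) / floor(1)
  expect_equal(s$intensity, 900)
  expect_equal(s$fast, 10)              # 0-based centroid of 10:12 block
  expect_equal(s$slow, 10)
  expect_false(s$is_saturated)
})

test_that("saturation flag follows the configured level", {
  panel <- matrix(0L, 15, 15)
  panel[7:8, 7:8] <- c(100L, 100L, 100L, 324L)
  sl <- find_spots(make_cal_frame(list(panel)),
                   spot_find_params(min_snr = 0, saturation_value = 324))
  expect_true(sl$spots$is_saturated[1])
  expect_identical(sl$n_saturated, 1L)
})

test_that("area filter rejects out-of-range components and counts them", {
  blob <- matrix(0L, 30, 30)
  blob[5:24, 5:14] <- 100L              # 200-pixel blob
  sl <- find_spots(make_cal_frame(list(blob)), spot_find_params())
  expect_identical(nrow(sl$spots), 0L)
  expect_identical(sl$n_rejected_area, 1L)
  empty <- find_spots(make_cal_frame(list(matrix(0L, 10, 10))))
  expect_identical(nrow(empty$spots), 0L)
  expect_identical(empty$n_rejected_area + empty$n_rejected_snr, 0L)
})

test_that("raising thresholds never increases the accepted count", {
  run <- default_mini_run()
  dark <- mini_dark(run)
  i <- which(run$truth$frames$is_hit)[2]
  cal <- calibrate(get_frame(run, i), dark,
                   calibration_params(gains = run$geometry$gains))
  base <- spot_find_params()
  n0 <- nrow(find_spots(cal, base)$spots)
  for (p in list(spot_find_params(pixel_threshold = 80),
                 spot_find_params(min_snr = 20),
                 spot_find_params(min_area = 3),
                 spot_find_params(pixel_threshold = 120, min_snr = 50,
                                  min_area = 4))) {
    expect_lte(nrow(find_spots(cal, p)$spots), n0)
  }
})

test_that("recovery is exact for strong well-separated spots", {
  run <- strong_mini_run()
  dark <- mini_dark(run)
  hits <- which(run$truth$frames$is_hit)
  for (i in hits[1:8]) {
    cal <- calibrate(get_frame(run, i), dark)
    sl <- find_spots(cal, strong_spot_params())
    truth <- run$truth$spots[run$truth$spots$frame_index == i, ]
    expect_identical(nrow(sl$spots), nrow(truth))
    mt <- match_spots(sl, truth, radius = 1)   # centroid error <= 1 px
    expect_equal(mt$recall, 1.0)
    expect_equal(mt$precision, 1.0)
    # integrated intensity within Poisson error of planted photons x 10.
    # A low threshold (1 photon) makes the component footprint capture
    # ~97% of the Gaussian mass; the residual truncation is well inside
    # the Poisson band for 400-photon spots.
    low <- find_spots(cal, spot_find_params(pixel_threshold = 10,
                                            min_area = 4))$spots
    for (k in seq_len(nrow(truth))) {
      d <- sqrt((low$fast - truth$fast[k])^2 +
                  (low$slow - truth$slow[k])^2)
      j <- which(low$module == truth$module[k] & d <= 1.5)
      expect_length(j, 1L)
      expect_lt(abs(low$intensity[j] - truth$photons[k] * 10),
                4 * sqrt(truth$photons[k]) * 10 + 200)
    }
  }
})

test_that("components never merge across panel boundaries", {
  # one blob straddling the panel seam in lab space: bottom rows of panel
  # 1 and top rows of panel 2
  p1 <- matrix(0L, 16, 16); p2 <- matrix(0L, 16, 16)
  p1[15:16, 8:9] <- 200L
  p2[1:2, 8:9] <- 200L
  sl <- find_spots(make_cal_frame(list(p1, p2)),
                   spot_find_params(min_snr = 0))
  expect_identical(nrow(sl$spots), 2L)
  expect_identical(sort(sl$spots$module), c(0L, 1L))
})

test_that("spot lists serialize to a stream-style text block", {
  run <- strong_mini_run()
  dark <- mini_dark(run)
  i <- which(run$truth$frames$is_hit)[1]
  sl <- find_spots(calibrate(get_frame(run, i), dark))
  path <- withr::local_tempfile(fileext = ".stream")
  write_peaks_stream(list(sl), path)
  txt <- readLines(path)
  expect_true(any(grepl("Peaks from peak search", txt)))
  expect_identical(sum(grepl("^\\s+-?[0-9.]+\\s+-?[0-9.]+", txt)),
                   nrow(sl$spots))
})
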