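test_that("matching handles the trivial cases", {
  found <- data.frame(module = 0L, fast = c(5, 20), slow = c(5, 20))
  exact <- match_spots(found, found)
  expect_equal(exact$recall, 1); expect_equal(exact$precision, 1)
  expect_equal(exact$f1, 1)
  none <- match_spots(found[0, ], found)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 1)      # nothing found, nothing wrong
  # cross-panel centroids never match
  other <- data.frame(module = 1L, fast = 5, slow = 5)
  expect_equal(match_spots(found, other)$n_matched, 0L)
})

test_that("greedy matching is near-optimal on perturbed spot sets", {
  set.seed(53)
  tot_g <- 0L; tot_o <- 0L; tot_t <- 0L
  for (k in 1:100) {
    n <- sample(3:7, 1)
    truth <- data.frame(module = sample(0:1, n, replace = TRUE),
                        fast = runif(n, 5, 55), slow = runif(n, 5, 55))
    found <- truth
    found$fast <- found$fast + runif(n, -1.4, 1.4)
    found$slow <- found$slow + runif(n, -1.4, 1.4)
    # a few spurious detections
    found <- rbind(found, data.frame(module = 0L, fast = runif(2, 5, 55),
                                     slow = runif(2, 5, 55)))
    tot_g <- tot_g + match_spots(found, truth)$n_matched
    tot_o <- tot_o + optimal_match_count(found, truth)
    tot_t <- tot_t + n
  }
  f1 <- function(m) 2 * m / (tot_t + tot_t + 200)
  expect_lte(tot_g, tot_o)
  expect_lt(f1(tot_o) - f1(tot_g), 0.02)
})

test_that("grid search is exhaustive, reproducible, with tie-breaks", {
  run <- strong_mini_run()
  g1 <- grid_search(run, param_grid(pixel_threshold = 50, n_eval = 5),
                    spot_params = strong_spot_params())
  expect_identical(nrow(g1$table), 1L)
  expect_identical(g1$best$pixel_threshold, 50)
  g2 <- grid_search(run, param_grid(pixel_threshold = c(50, 80),
                                    min_snr = c(3, 5), n_eval = 5),
                    spot_params = strong_spot_params())
  expect_identical(nrow(g2$table), 4L)
  g2b <- grid_search(run, param_grid(pixel_threshold = c(50, 80),
                                     min_snr = c(3, 5), n_eval = 5),
                     spot_params = strong_spot_params())
  expect_identical(g2$table, g2b$table)
  # strong spots are recovered perfectly in every cell here: the tie
  # breaks toward the most permissive parameters
  expect_true(all(abs(g2$table$f1 - 1) < 1e-9))
  expect_identical(g2$best$pixel_threshold, 50)
  expect_identical(g2$best$min_snr, 3)
  expect_error(grid_search(run, param_grid(beam_dx = 0:1)), "beam-center")
  expect_error(param_grid(), "named axis")
  expect_error(param_grid(nonsense = 1:3), "unknown grid axes")
})

test_that("recall is non-increasing along a rising threshold axis", {
  run <- default_mini_run()
  g <- grid_search(run, param_grid(pixel_threshold = c(30, 50, 90, 150,
                                                       280),
                                   n_eval = 8),
                   objective = "recall")
  tab <- g$table[order(g$table$pixel_threshold), ]
  expect_true(all(diff(tab$recall) <= 1e-12))
})

test_that("a grid spanning the planted regime reaches F1 >= 0.95", {
  run <- default_mini_run()
  g <- grid_search(run, param_grid(pixel_threshold = c(50, 100),
                                   min_area = c(1L, 2L), n_eval = 25))
  expect_gte(max(g$table$f1), 0.95)
  expect_equal(g$best$f1, max(g$table$f1))
})

test_that("beam-center scan recovers a planted offset within one step", {
  # generate with the beam (and hence the ring) shifted by +2 px along
  # the stacking axis, analyse with the nominal geometry.  The ring
  # crosses the narrow panels in near-horizontal arcs, so the stacking
  # (y) offset is the well-conditioned axis of the radial-spread scan.
  shift_px <- 2
  px <- 0.05
  gen_geom <- mini_geometry()
  gen_geom$beam_center_mm <- c(0, shift_px * px)  # beam moves, panels stay
  run <- cached_run("shifted_ring", function() synthetic_run(
    run_manifest(n_dark = 4, n_exposed = 6),
    sim_params(hit_fraction = 0, ring_radius_px = 150, ring_width_px = 6,
               ring_peak_photons = 40, seed = 59),
    gen_geom))
  # analysis geometry believes the beam is at the origin
  run$geometry <- mini_geometry()
  scan <- scan_beam_center(run, offsets_x = 0, offsets_y = -4:4,
                           n_eval = 4)
  best <- attr(scan, "best")
  expect_lte(abs(best$beam_dy - shift_px), 1)
  expect_identical(best$beam_dx, 0)
})

test_that("best parameters export as a config snippet", {
  run <- strong_mini_run()
  g <- grid_search(run, param_grid(pixel_threshold = c(50, 80), n_eval = 3),
                   spot_params = strong_spot_params())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_best_params(g, path)
  y <- yaml::read_yaml(path)
  expect_identical(y$pixel_threshold, g$best$pixel_threshold)
})
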