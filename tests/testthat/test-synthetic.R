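test_that("run layout: dark block then exposed block, unique tags", {
  man <- run_manifest()   # standard run
  run <- synthetic_run(man, sim_params(), detector_geometry())
  fr <- run$truth$frames
  expect_identical(nrow(fr), 5150L)
  expect_identical(sum(!fr$shutter_open), 150L)
  expect_false(any(fr$is_hit[!fr$shutter_open]))
  expect_false(anyDuplicated(fr$tag) > 0)
  expect_true(all(diff(fr$tag) == 1))
})

test_that("degenerate parameters behave as stated", {
  run <- synthetic_run(run_manifest(n_dark = 2, n_exposed = 30),
                       sim_params(hit_fraction = 0, seed = 9),
                       mini_geometry())
  expect_false(any(run$truth$frames$is_hit))
  expect_identical(nrow(run$truth$spots), 0L)
  expect_error(
    synthetic_run(run_manifest(n_dark = 2, n_exposed = 2),
                  sim_params(hit_fraction = 0.5, spots_per_hit_mean = 0),
                  mini_geometry()),
    "spots_per_hit_mean")
})

test_that("hit count is binomial: within 3 sigma of n * hit_fraction", {
  run <- synthetic_run(run_manifest(n_dark = 1, n_exposed = 500),
                       sim_params(hit_fraction = 0.4, seed = 21),
                       mini_geometry())
  hits <- sum(run$truth$frames$is_hit)
  expect_lt(abs(hits - 500 * 0.4), 3 * sqrt(500 * 0.4 * 0.6))
})

test_that("generation is deterministic and access-order independent", {
  make <- function() synthetic_run(run_manifest(n_dark = 2, n_exposed = 4),
                                   strong_params(seed = 77),
                                   mini_geometry())
  r1 <- make(); r2 <- make()
  expect_identical(r1$truth, r2$truth)
  f3a <- get_frame(r1, 3)
  f5 <- get_frame(r1, 5)          # different access order on r2
  expect_identical(get_frame(r2, 5)$panels, f5$panels)
  expect_identical(get_frame(r2, 3)$panels, f3a$panels)
  # rendering does not disturb the caller's RNG
  set.seed(123); x <- rnorm(1)
  set.seed(123); invisible(get_frame(r1, 2)); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("dark frames carry pedestal and read noise only", {
  run <- strong_mini_run()
  f <- get_frame(run, 1)
  expect_false(f$shutter_open)
  p <- run$params
  for (panel in f$panels) {
    expect_true(all(panel >= 0 & panel <= 65535))
    expect_lt(abs(mean(panel) - p$pedestal_adu),
              5 * p$read_noise_adu / sqrt(length(panel)))
  }
})

test_that("planted spot charge inverts the calibration model", {
  # integrated ADU above pedestal ~= photons * E / (3.65 * gain),
  # Poisson-limited: generator consistency with the calibration model
  run <- strong_mini_run()
  i <- which(run$truth$frames$is_hit)[1]
  f <- get_frame(run, i)
  sp <- run$truth$spots[run$truth$spots$frame_index == i, ]
  expect_gt(nrow(sp), 0)
  epe <- run$manifest$photon_energy_ev / 3.65
  for (k in seq_len(nrow(sp))) {
    expect_false(sp$is_saturated[k])
    panel <- f$panels[[sp$module[k] + 1L]]
    rows <- pmax(1, round(sp$slow[k]) - 7):pmin(nrow(panel),
                                                round(sp$slow[k]) + 9)
    cols <- pmax(1, round(sp$fast[k]) - 7):pmin(ncol(panel),
                                                round(sp$fast[k]) + 9)
    got <- sum(panel[rows, cols] - run$params$pedestal_adu)
    want <- sp$photons[k] * epe
    tol <- 4 * sqrt(sp$photons[k]) * epe +
      5 * run$params$read_noise_adu * sqrt(length(rows) * length(cols))
    expect_lt(abs(got - want), tol)
  }
})

test_that("saturated spots are clipped and flagged", {
  run <- synthetic_run(
    run_manifest(n_dark = 2, n_exposed = 6),
    sim_params(hit_fraction = 1, spots_per_hit_mean = 5,
               spot_photons_meanlog = log(2000), spot_photons_sdlog = 0,
               ring_peak_photons = 0, min_separation_px = 12, seed = 31),
    mini_geometry())
  sp <- run$truth$spots
  expect_true(all(sp$is_saturated))   # peak ~142 photons >> 32.4 clip
  i <- sp$frame_index[1]
  f <- get_frame(run, i)
  expect_true(all(vapply(f$panels, max, numeric(1)) <=
                    run$params$saturation_adu))
  expect_identical(max(f$panels[[sp$module[1] + 1L]]),
                   as.integer(run$params$saturation_adu))
})

test_that("pump-probe schedule separates light and dark", {
  man <- run_manifest(n_dark = 1, n_exposed = 10, pump_probe = TRUE)
  set.seed(1)
  sched <- pump_probe_schedule(man)
  expect_identical(sum(sched$pump_state == "light"), 5L)
  expect_identical(sum(sched$pump_state == "dark"), 5L)
  set.seed(1)
  alldark <- pump_probe_schedule(man, pattern = "dark")
  expect_true(all(alldark$photodiode < 0.5))
  expect_error(pump_probe_schedule(man, pattern = character(0)), "pattern")
  expect_error(pump_probe_schedule(run_manifest()), "pump_probe")
  # random pattern recovers requested proportions within 3 sigma
  man2 <- run_manifest(n_dark = 1, n_exposed = 1000, pump_probe = TRUE)
  set.seed(2)
  s2 <- pump_probe_schedule(man2, p_light = 0.7)
  expect_lt(abs(sum(s2$pump_state == "light") - 700),
            3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("ground-truth invariants hold on the default mini world", {
  run <- default_mini_run()
  fr <- run$truth$frames
  sp <- run$truth$spots
  expect_true(all(fr$n_spots[fr$is_hit] >= 1))
  expect_identical(sum(fr$n_spots), nrow(sp))
  for (k in seq_len(nrow(sp))) {
    p <- run$geometry$panels[[sp$module[k] + 1L]]
    expect_true(sp$fast[k] >= 0 && sp$fast[k] <= p$fast_extent - 1)
    expect_true(sp$slow[k] >= 0 && sp$slow[k] <= p$slow_extent - 1)
  }
  expect_true(all(fr$has_ring == fr$shutter_open))
})

test_that("truth TSV export is well-formed", {
  run <- strong_mini_run()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(run, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), n_frames(run))
  expect_identical(as.logical(tab$is_hit), run$truth$frames$is_hit)
})
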