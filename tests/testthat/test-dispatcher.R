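test_that("a tag dispatches exactly when all eight watermarks cover it", {
  tr <- tag_tracker()
  for (m in 0:6) advance(tr, m, 10)
  expect_length(dispatched_tags(tr), 0L)
  res <- advance(tr, 7, 10)
  expect_identical(res$dispatched, 10)
  expect_identical(dispatched_tags(tr), 10)
  # one module running ahead does not dispatch anything
  tr2 <- tag_tracker()
  advance(tr2, 0, 10)
  expect_length(dispatched_tags(tr2), 0L)
})

test_that("watermark regression is a contract violation", {
  tr <- tag_tracker()
  advance(tr, 3, 5)
  expect_error(advance(tr, 3, 4), "regression")
  expect_error(advance(tr, 3, 5), "regression")
  expect_error(advance(tr, 9, 1), "out of range")
})

test_that("tags a module skipped are reported as skipped", {
  tr <- tag_tracker()
  for (m in 0:7) advance(tr, m, 1)
  # module 3 skips tag 2 and goes straight to 3
  for (m in setdiff(0:7, 3)) advance(tr, m, 2)
  for (m in setdiff(0:7, 3)) advance(tr, m, 3)
  res <- advance(tr, 3, 3)          # min watermark passes 2 without it
  expect_identical(res$dispatched, 3)
  expect_identical(skipped_tags(tr), 2)
  expect_identical(dispatched_tags(tr), c(1, 3))
})

test_that("dispatch equals the min-watermark oracle over 10,000 advances", {
  set.seed(37)
  n_tags <- 1250L
  tr <- tag_tracker()
  ptr <- rep(0L, 8)                  # per-module position in the tag list
  wm <- rep(-Inf, 8)
  oracle <- numeric(0)               # brute-force dispatch sequence
  steps <- 0L
  while (any(ptr < n_tags)) {
    live <- which(ptr < n_tags)
    m <- live[sample.int(length(live), 1)]
    ptr[m] <- ptr[m] + 1L
    tag <- as.numeric(ptr[m])
    res <- advance(tr, m - 1L, tag)
    steps <- steps + 1L
    wm[m] <- tag
    # oracle: all tags covered by the minimum watermark, ascending
    covered <- seq_len(max(0, min(wm)))
    newly <- setdiff(covered, oracle)
    oracle <- c(oracle, sort(newly))
    expect_identical(res$dispatched, as.numeric(sort(newly)))
  }
  expect_identical(steps, 8L * n_tags)
  expect_identical(dispatched_tags(tr), oracle)
  expect_identical(dispatched_tags(tr), sort(dispatched_tags(tr)))
  expect_length(skipped_tags(tr), 0L)
})

test_that("split_run partitions exposed frames near-equally", {
  man <- run_manifest()              # 5000 exposed
  parts <- split_run(man, 3)
  expect_identical(lengths(parts), c(1667L, 1667L, 1666L))
  expect_identical(sort(unlist(parts)), 1:5000)
  expect_identical(split_run(man, 1)[[1]], 1:5000)
  expect_error(split_run(run_manifest(n_exposed = 2), 3), "more jobs")
  expect_error(split_run(man, 0), "at least 1")
})

test_that("processing a run end to end matches the ground truth", {
  run <- strong_mini_run()
  cfg <- pipeline_config(run$geometry, spot = strong_spot_params())
  out <- withr::local_tempdir()
  res <- process_run(run, cfg, out)
  fr <- run$truth$frames[run$truth$frames$shutter_open, ]
  # unambiguous strong frames: pipeline hits = frames with >= 20 planted
  # spots (generator hits can have fewer spots than the hit rule demands)
  expect_identical(res$hits$is_hit, fr$n_spots >= 20L)
  expect_identical(res$summary$n_hits, sum(fr$n_spots >= 20L))
  expect_identical(sort(list_tags(res$paths$events)),
                   sort(fr$tag[fr$n_spots >= 20L]))
  expect_true(file.exists(res$paths$monitor_log))
})

test_that("hit_fraction 0 yields an empty store and zero hit rate", {
  run <- cached_run("blank_mini", function() synthetic_run(
    run_manifest(n_dark = 3, n_exposed = 10),
    sim_params(hit_fraction = 0, ring_peak_photons = 0, seed = 41),
    mini_geometry()))
  res <- process_run(run, pipeline_config(run$geometry),
                     withr::local_tempdir())
  expect_identical(res$summary$n_hits, 0L)
  expect_equal(res$summary$hit_rate, 0)
  expect_identical(list_tags(res$paths$events), numeric(0))
})

test_that("re-processing reproduces byte-identical logs and tag sets", {
  run <- strong_mini_run()
  cfg <- pipeline_config(run$geometry, spot = strong_spot_params())
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  r1 <- process_run(run, cfg, o1)
  r2 <- process_run(run, cfg, o2)
  expect_identical(readLines(r1$paths$monitor_log),
                   readLines(r2$paths$monitor_log))
  expect_identical(list_tags(r1$paths$events), list_tags(r2$paths$events))
})

test_that("split processing merges to the unsplit result (k = 1,2,3,5)", {
  run <- cached_run("split_mini", function() synthetic_run(
    run_manifest(n_dark = 4, n_exposed = 60),
    strong_params(seed = 43, hit_fraction = 0.5), mini_geometry()))
  cfg <- pipeline_config(run$geometry, spot = strong_spot_params())
  whole <- process_run(run, cfg, withr::local_tempdir(),
                       write_store = FALSE)$hits
  rownames(whole) <- NULL
  for (k in c(2L, 3L, 5L)) {
    parts <- split_run(run$manifest, k)
    merged <- do.call(rbind, lapply(parts, function(p)
      process_run(run, cfg, withr::local_tempdir(), frames = p,
                  write_store = FALSE)$hits))
    rownames(merged) <- NULL
    expect_equal(merged, whole)
  }
})

test_that("pump-probe runs route light and dark hits to separate stores", {
  def <- fixture_definition("pump-probe-run")
  run <- cached_run("pump_mini_strong", function() synthetic_run(
    run_manifest(n_dark = 4, n_exposed = 30, pump_probe = TRUE,
                 run_id = 55),
    strong_params(seed = 47), mini_geometry()))
  cfg <- pipeline_config(run$geometry, spot = strong_spot_params())
  res <- process_run(run, cfg, withr::local_tempdir())
  fr <- run$truth$frames[run$truth$frames$shutter_open, ]
  want_hit <- fr$n_spots >= 20L
  lt <- list_tags(res$paths$events_light)
  dk <- list_tags(res$paths$events_dark)
  expect_identical(sort(c(lt, dk)), sort(fr$tag[want_hit]))
  expect_identical(sort(lt), sort(fr$tag[want_hit &
                                           fr$pump_state == "light"]))
  expect_identical(res$summary$n_light + res$summary$n_dark_state,
                   nrow(fr))
})
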