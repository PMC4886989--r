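#' Tag-completeness tracker (producer-consumer contract)
#'
#' The acquisition side of the pipeline reads each detector module in its
#' own stream; a frame may be processed only once all eight module panels
#' for its tag have arrived.  The tracker keeps one watermark per module
#' -- the latest tag that module has delivered -- and dispatches a tag as
#' soon as every watermark has reached it.  Per-module deliveries must be
#' strictly increasing in tag (a regression is a contract violation).  A
#' tag that some module skipped is marked `skipped` once the minimum
#' watermark has passed it by more than `lag`.
#'
#' This is a sequential data structure modelling the concurrent design:
#' per-module watermark writes are single-writer, and the dispatch check
#' reads all watermarks; under that contract no locking is required.
#'
#' @param n_modules number of module streams (8).
#' @param lag grace distance (in tags) before an incomplete tag is
#'   declared skipped (default 0: skip as soon as it is surpassed).
#' @return an `sfx_tag_tracker`.
#' @export
tag_tracker <- function(n_modules = 8L, lag = 0) {
  e <- new.env()
  e$watermarks <- rep(-Inf, n_modules)
  e$pending <- new.env(hash = TRUE)   # tag string -> n modules delivered
  e$dispatched <- numeric(0)
  e$skipped <- numeric(0)
  structure(list(n_modules = as.integer(n_modules), lag = lag, env = e),
            class = "sfx_tag_tracker")
}

#' Advance one module's watermark
#'
#' Records that `module` has delivered the panel for `tag` and returns the
#' tags that thereby became dispatchable (in ascending order), plus any
#' tags newly declared skipped.
#'
#' @param tracker an [tag_tracker()].
#' @param module 0-based module index.
#' @param tag delivered tag number (must exceed the module's watermark).
#' @return list with `dispatched` and `skipped` numeric vectors.
#' @export
advance <- function(tracker, module, tag) {
  stopifnot(inherits(tracker, "sfx_tag_tracker"))
  e <- tracker$env
  m <- module + 1L
  if (m < 1L || m > tracker$n_modules) stop("module index out of range")
  if (tag <= e$watermarks[m])
    stop(sprintf(
      "watermark regression on module %d: tag %.0f after %.0f",
      module, tag, e$watermarks[m]))
  e$watermarks[m] <- tag
  key <- sprintf("%.0f", tag)
  cnt <- (if (exists(key, envir = e$pending, inherits = FALSE))
    get(key, envir = e$pending) else 0L) + 1L
  newly <- numeric(0)
  if (cnt == tracker$n_modules) {
    # all modules delivered; every watermark >= tag by construction
    rm(list = key, envir = e$pending)
    e$dispatched <- c(e$dispatched, tag)
    newly <- tag
  } else {
    assign(key, cnt, envir = e$pending)
  }
  # incomplete tags overtaken by all modules are skipped
  low <- min(e$watermarks)
  skipped <- numeric(0)
  if (is.finite(low)) {
    pend <- as.numeric(ls(e$pending))
    old <- pend[pend + tracker$lag < low]
    if (length(old)) {
      rm(list = sprintf("%.0f", old), envir = e$pending)
      old <- sort(old)
      e$skipped <- c(e$skipped, old)
      skipped <- old
    }
  }
  list(dispatched = newly, skipped = skipped)
}

#' Tracker state accessors
#'
#' @param tracker an [tag_tracker()].
#' @return `dispatched_tags`/`skipped_tags`: tags in dispatch/skip order;
#'   `watermarks`: current per-module watermarks.
#' @export
dispatched_tags <- function(tracker) tracker$env$dispatched

#' @rdname dispatched_tags
#' @export
skipped_tags <- function(tracker) tracker$env$skipped

#' @rdname dispatched_tags
#' @export
watermarks <- function(tracker) tracker$env$watermarks

#' Full pipeline configuration
#'
#' Bundles the per-stage parameter objects and the output conventions for
#' [process_run()].  Defaults are internally consistent with the default
#' synthetic detector model; note the LLF threshold of 20 photons (not
#' the facility's ~50), because the unit-gain detector clips at ~32
#' photons/pixel -- see [hit_params()] and the methods vignette.
#'
#' @param geometry an [detector_geometry()].
#' @param cal an [calibration_params()]; gains default to the geometry's.
#' @param spot an [spot_find_params()].
#' @param hit an [hit_params()].
#' @param store an [store_config()].
#' @param monitor_window rolling window for the hit-rate monitor.
#' @param pump_threshold photodiode threshold for light/dark states.
#' @return an `sfx_pipeline_config`.
#' @export
pipeline_config <- function(geometry = detector_geometry(),
                            cal = calibration_params(
                              gains = geometry$gains),
                            spot = spot_find_params(),
                            hit = hit_params(llf_threshold = 20),
                            store = store_config(),
                            monitor_window = 100L,
                            pump_threshold = 0.5) {
  structure(list(geometry = geometry, cal = cal, spot = spot, hit = hit,
                 store = store, monitor_window = as.integer(monitor_window),
                 pump_threshold = pump_threshold),
            class = "sfx_pipeline_config")
}

#' Process a run end to end
#'
#' Runs the full offline chain on a synthetic run: build the dark
#' reference from the dark block, then for every exposed frame calibrate,
#' LLF-pre-filter, find spots, classify the hit (and pump-probe state when
#' applicable), update the monitor, and append hits to the multi-event
#' store.  For pump-probe runs, light and dark hits are routed to
#' separate stores (`events_light.h5` / `events_dark.h5`); otherwise a
#' single `events.h5` is written.  The monitor log and a run summary are
#' written as TSV.  Fully deterministic: re-running with the same run and
#' configuration reproduces byte-identical logs and the same tag sets.
#'
#' @param run an [synthetic_run()].
#' @param config an [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param frames optional subset of exposed-frame indices (1-based within
#'   the exposed block) to process, as produced by [split_run()]; the
#'   dark block is always available to every job.
#' @param write_store set `FALSE` to skip HDF5 output (monitoring only).
#' @return list with `summary` (one-row data.frame), `hits` (per-frame
#'   table: tag, llf_value, n_spots, n_saturated, is_hit, pump_state),
#'   `paths` of written artifacts, and the `monitor`.
#' @export
process_run <- function(run, config = pipeline_config(run$geometry),
                        out_dir = tempfile("sfxrun"), frames = NULL,
                        write_store = TRUE) {
  stopifnot(inherits(run, "sfx_run"),
            inherits(config, "sfx_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- run$manifest
  if (man$n_dark < 1L) stop("run has no dark block; cannot calibrate")
  dark <- compute_dark(run)
  frames <- frames %||% seq_len(man$n_exposed)
  stopifnot(all(frames >= 1L & frames <= man$n_exposed))

  mon <- hit_monitor(config$monitor_window)
  pump <- isTRUE(man$pump_probe)
  stores <- list()
  paths <- list(monitor_log = file.path(out_dir, "monitor.tsv"),
                summary = file.path(out_dir, "summary.tsv"))
  meta <- list(run_id = man$run_id,
               photon_energy_ev = man$photon_energy_ev,
               parameters = yaml::as.yaml(list(
                 pixel_threshold = config$spot$pixel_threshold,
                 min_snr = config$spot$min_snr,
                 min_area = config$spot$min_area,
                 max_area = config$spot$max_area,
                 min_spots = config$hit$min_spots,
                 llf_mode = config$hit$llf_mode,
                 llf_threshold = config$hit$llf_threshold,
                 deflate_level = config$store$level)))
  if (write_store) {
    if (pump) {
      paths$events_light <- file.path(out_dir, "events_light.h5")
      paths$events_dark <- file.path(out_dir, "events_dark.h5")
      stores$light <- open_event_store(paths$events_light, config$store,
                                       meta)
      stores$dark <- open_event_store(paths$events_dark, config$store, meta)
    } else {
      paths$events <- file.path(out_dir, "events.h5")
      stores$all <- open_event_store(paths$events, config$store, meta)
    }
  }

  rows <- vector("list", length(frames))
  pump_states <- character(length(frames))
  for (k in seq_along(frames)) {
    i <- man$n_dark + frames[k]
    raw <- get_frame(run, i)
    cal <- calibrate(raw, dark, config$cal)
    llf <- llf_prefilter(cal, config$hit)
    spots <- find_spots(cal, config$spot)
    state <- if (pump) classify_pump_state(raw, config$pump_threshold)
      else "n/a"
    decision <- classify_hit(spots, config$hit, llf$passed, state)
    monitor_update(mon, decision, spots)
    pump_states[k] <- state
    rows[[k]] <- data.frame(tag = cal$tag, llf_value = llf$llf_value,
                            n_spots = decision$n_spots,
                            n_saturated = spots$n_saturated,
                            is_hit = decision$is_hit, pump_state = state)
    if (decision$is_hit && write_store) {
      ev <- event_record(cal, spots)
      if (pump) append_event(stores[[state]], ev)
      else append_event(stores$all, ev)
    }
  }
  for (s in stores) close_event_store(s)

  hits <- do.call(rbind, rows) %||%
    data.frame(tag = numeric(0), llf_value = numeric(0),
               n_spots = integer(0), n_saturated = integer(0),
               is_hit = logical(0), pump_state = character(0))
  write_monitor_log(mon, paths$monitor_log)
  samples <- monitor_samples(mon)
  samples$pump_state <- pump_states
  summary <- summarize_run(samples, run_id = man$run_id)
  utils::write.table(summary, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(summary = summary, hits = hits, paths = paths, monitor = mon)
}

#' Partition a run's exposed frames into jobs
#'
#' Contiguous, disjoint, covering ranges of near-equal size (earlier jobs
#' take the remainder), mirroring the offline layout of several jobs per
#' run; every job re-uses the same dark block.
#'
#' @param manifest a [run_manifest()].
#' @param n_jobs number of jobs (default 3).
#' @return list of integer vectors of exposed-frame indices (1-based
#'   within the exposed block).
#' @export
split_run <- function(manifest, n_jobs = 3L) {
  n <- manifest$n_exposed
  if (n_jobs < 1L) stop("n_jobs must be at least 1")
  if (n_jobs > n) stop("more jobs than exposed frames")
  sizes <- rep(n %/% n_jobs, n_jobs) + (seq_len(n_jobs) <= n %% n_jobs)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_jobs), function(j) seq.int(starts[j], ends[j]))
}
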