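#' Streaming hit-rate monitor
#'
#' Real-time feedback accumulator: for every exposed frame it records the
#' spot and saturated-spot counts and the hit decision, and maintains a
#' rolling hit rate over the last `window` exposed frames (count-based,
#' default 100) or cumulatively.  Mirrors the online monitor trace of
#' spots / saturated spots / hit rate used to steer data collection.
#'
#' @param window rolling window length in exposed frames.
#' @param mode `"windowed"` (default) or `"cumulative"`.
#' @return an `sfx_monitor` accumulator.
#' @export
hit_monitor <- function(window = 100L, mode = c("windowed", "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(window >= 1L)
  e <- new.env()
  e$tag <- numeric(0); e$n_spots <- integer(0)
  e$n_saturated <- integer(0); e$is_hit <- logical(0)
  e$rate <- numeric(0)
  structure(list(window = as.integer(window), mode = mode, env = e),
            class = "sfx_monitor")
}

#' Record one frame in the monitor
#'
#' Appends a sample and returns it with the updated rolling hit rate.
#'
#' @param monitor an [hit_monitor()].
#' @param decision an `sfx_hit_decision` for an exposed frame.
#' @param spots the matching `sfx_spotlist`.
#' @return one-row data.frame: `tag`, `n_spots`, `n_saturated`, `is_hit`,
#'   `rolling_hit_rate`.
#' @export
monitor_update <- function(monitor, decision, spots) {
  stopifnot(inherits(monitor, "sfx_monitor"),
            inherits(decision, "sfx_hit_decision"),
            inherits(spots, "sfx_spotlist"))
  e <- monitor$env
  e$tag <- c(e$tag, decision$tag)
  e$n_spots <- c(e$n_spots, decision$n_spots)
  e$n_saturated <- c(e$n_saturated, spots$n_saturated)
  e$is_hit <- c(e$is_hit, decision$is_hit)
  n <- length(e$is_hit)
  rate <- if (monitor$mode == "windowed")
    mean(e$is_hit[max(1L, n - monitor$window + 1L):n])
  else mean(e$is_hit)
  e$rate <- c(e$rate, rate)
  data.frame(tag = decision$tag, n_spots = decision$n_spots,
             n_saturated = spots$n_saturated, is_hit = decision$is_hit,
             rolling_hit_rate = rate)
}

#' Samples recorded so far
#'
#' @param monitor an [hit_monitor()].
#' @return data.frame of all samples in arrival order.
#' @export
monitor_samples <- function(monitor) {
  e <- monitor$env
  data.frame(tag = e$tag, n_spots = e$n_spots, n_saturated = e$n_saturated,
             is_hit = e$is_hit, rolling_hit_rate = e$rate)
}

#' Summarize a completed run
#'
#' Totals over the exposed frames of a run; the dark block never enters
#' the hit-rate denominator.  Summaries are additive across runs: summing
#' `n_frames`/`n_hits` over runs matches a pooled summary.
#'
#' @param x an `sfx_monitor` or a samples data.frame (as returned by
#'   [monitor_samples()], optionally with a `pump_state` column).
#' @param run_id run identifier carried into the table.
#' @return one-row data.frame: `run_id`, `n_frames`, `n_hits`, `hit_rate`,
#'   `n_saturated_frames`, `n_light`, `n_dark_state`, `degenerate` (flag,
#'   `TRUE` when there were no exposed frames and the rate is reported 0).
#' @export
summarize_run <- function(x, run_id = NA_integer_) {
  s <- if (inherits(x, "sfx_monitor")) monitor_samples(x) else x
  n <- nrow(s)
  degenerate <- n == 0L
  pump <- if ("pump_state" %in% names(s)) s$pump_state else character(0)
  data.frame(run_id = run_id,
             n_frames = n,
             n_hits = if (degenerate) 0L else sum(s$is_hit),
             hit_rate = if (degenerate) 0 else mean(s$is_hit),
             n_saturated_frames = if (degenerate) 0L else
               sum(s$n_saturated > 0),
             n_light = sum(pump == "light"),
             n_dark_state = sum(pump == "dark"),
             degenerate = degenerate)
}

#' Write / read the plain-text monitor log
#'
#' Append-only TSV (`tag`, `n_spots`, `n_saturated`, `is_hit`,
#' `rolling_hit_rate`), mirroring the online stage that writes only spot
#' finding results, never images.  The log is sufficient to reconstruct
#' the monitor state ([read_monitor_log()]), which is what makes crash
#' recovery by re-reading logs possible.
#'
#' @param monitor an [hit_monitor()].
#' @param path log file path.
#' @export
write_monitor_log <- function(monitor, path) {
  s <- monitor_samples(monitor)
  s$tag <- sprintf("%.0f", s$tag)
  s$rolling_hit_rate <- sprintf("%.6f", s$rolling_hit_rate)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_monitor_log
#' @param window,mode monitor settings to rebuild with.
#' @return `read_monitor_log` returns an `sfx_monitor` whose state equals
#'   the writer's.
#' @export
read_monitor_log <- function(path, window = 100L,
                             mode = c("windowed", "cumulative")) {
  s <- utils::read.table(path, header = TRUE, sep = "\t")
  mon <- hit_monitor(window, match.arg(mode))
  e <- mon$env
  e$tag <- as.numeric(s$tag)
  e$n_spots <- as.integer(s$n_spots)
  e$n_saturated <- as.integer(s$n_saturated)
  e$is_hit <- as.logical(s$is_hit)
  e$rate <- as.numeric(s$rolling_hit_rate)
  mon
}

#' Plot the monitor trace
#'
#' Spot counts, saturated-spot counts and the rolling hit rate against
#' frame order, in the style of the online monitor display.
#'
#' @param x an `sfx_monitor`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sfx_monitor <- function(x, ...) {
  s <- monitor_samples(x)
  if (nrow(s) == 0L) stop("monitor has no samples")
  i <- seq_len(nrow(s))
  graphics::plot(i, s$n_spots, type = "h", col = "red",
                 xlab = "exposed frame", ylab = "spots / image", ...)
  graphics::points(i, s$n_saturated, type = "h", col = "blue")
  graphics::lines(i, s$rolling_hit_rate * max(1, max(s$n_spots)),
                  col = "blue", lwd = 2)
  invisible(x)
}
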