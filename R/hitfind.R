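#' Hit-classification parameters
#'
#' Two-stage hit finding: a cheap low-level filter (LLF) that computes the
#' maximum or mean photon value over a region of interest and rejects
#' obviously blank frames, followed by the spot-count rule -- a frame with
#' at least `min_spots` accepted spots is retained as a hit (inclusive
#' comparison; frames with fewer spots are low-resolution and can be
#' discarded without hurting the merged data set).
#'
#' The LLF threshold is in photons and the default follows the facility
#' practice of setting it very low (~50 photons) so that it only rejects
#' blanks.  Note that with the default unit-gain detector model the clip
#' level is ~32 photons/pixel, so a max-mode LLF at 50 photons rejects
#' everything; [pipeline_config()] therefore rescales its default to 20
#' photons (see the methods vignette).
#'
#' @param min_spots minimum accepted-spot count for a hit (default 20).
#' @param llf_mode `"max"` or `"mean"` over the ROI.
#' @param llf_threshold LLF pass threshold, photons.
#' @param roi region of interest: `NULL` for all pixels, or a list of
#'   per-panel logical matrices (`TRUE` = inside ROI).  See
#'   [ring_exclusion_roi()] for masking the carrier-medium ring.
#' @return an object of class `sfx_hit_params`.
#' @export
hit_params <- function(min_spots = 20L,
                       llf_mode = c("max", "mean"),
                       llf_threshold = 50,
                       roi = NULL) {
  llf_mode <- match.arg(llf_mode)
  stopifnot(min_spots >= 1L, llf_threshold >= 0)
  structure(list(min_spots = as.integer(min_spots), llf_mode = llf_mode,
                 llf_threshold = llf_threshold, roi = roi),
            class = "sfx_hit_params")
}

#' ROI excluding the carrier-medium ring
#'
#' Builds per-panel masks excluding pixels whose distance from the beam
#' axis (in pixel units) lies within `half_width` of `radius_px`.  The
#' carrier medium (grease, lipidic cubic phase) produces strong ring
#' scattering that defeats naive intensity filtering; excluding it from
#' the LLF ROI restores blank rejection.
#'
#' @param geometry an [detector_geometry()].
#' @param radius_px ring radius, pixels from the beam axis.
#' @param half_width exclusion half-width, pixels.
#' @return list of logical matrices (`TRUE` = keep).
#' @export
ring_exclusion_roi <- function(geometry, radius_px, half_width) {
  assert_geometry(geometry)
  bx <- geometry$beam_center_mm[1]; by <- geometry$beam_center_mm[2]
  lapply(geometry$panels, function(p) {
    f <- seq_len(p$fast_extent) - 1L
    s <- seq_len(p$slow_extent) - 1L
    x <- p$origin_lab[1] + outer(s * p$slow_axis[1], f * p$fast_axis[1],
                                 "+") * p$pixel_size
    y <- p$origin_lab[2] + outer(s * p$slow_axis[2], f * p$fast_axis[2],
                                 "+") * p$pixel_size
    r <- sqrt((x - bx)^2 + (y - by)^2) / p$pixel_size
    abs(r - radius_px) > half_width
  })
}

#' Low-level blank-rejection pre-filter
#'
#' Computes the maximum or mean photon value over the ROI of a calibrated
#' frame; the frame passes when the value reaches the threshold.
#'
#' @param frame an `sfx_cal_frame`.
#' @param params an [hit_params()].
#' @return list with `passed` (logical) and `llf_value` (photons).
#' @export
llf_prefilter <- function(frame, params = hit_params()) {
  stopifnot(inherits(frame, "sfx_cal_frame"),
            inherits(params, "sfx_hit_params"))
  ph <- photons(frame)
  vals <- if (is.null(params$roi)) {
    unlist(lapply(ph, as.numeric), use.names = FALSE)
  } else {
    if (length(params$roi) != length(ph))
      stop("ROI panel count does not match frame")
    unlist(lapply(seq_along(ph), function(m) ph[[m]][params$roi[[m]]]),
           use.names = FALSE)
  }
  if (length(vals) == 0L) stop("ROI is empty")
  llf_value <- if (params$llf_mode == "max") max(vals) else mean(vals)
  list(passed = llf_value >= params$llf_threshold, llf_value = llf_value)
}

#' Spot-count hit rule
#'
#' A frame is a hit iff it passed the LLF pre-filter and its accepted spot
#' count is at least `min_spots` (inclusive).
#'
#' @param spots an `sfx_spotlist` from [find_spots()].
#' @param params an [hit_params()].
#' @param llf_passed logical result of [llf_prefilter()] (default `TRUE`
#'   when no pre-filter is in use).
#' @param pump_state `"light"`, `"dark"` or `"n/a"` from
#'   [classify_pump_state()].
#' @return an `sfx_hit_decision`: `tag`, `passed_llf`, `n_spots`,
#'   `is_hit`, `pump_state`.
#' @export
classify_hit <- function(spots, params = hit_params(), llf_passed = TRUE,
                         pump_state = "n/a") {
  stopifnot(inherits(spots, "sfx_spotlist"),
            inherits(params, "sfx_hit_params"))
  n <- nrow(spots$spots)
  structure(list(tag = spots$tag,
                 passed_llf = isTRUE(llf_passed),
                 n_spots = n,
                 is_hit = isTRUE(llf_passed) && n >= params$min_spots,
                 pump_state = pump_state),
            class = "sfx_hit_decision")
}

#' Classify the pump-probe state of a frame
#'
#' Light iff the photodiode readout (pump-laser pickoff) is at or above
#' the threshold.  A missing readout yields `"n/a"` with a warning.
#'
#' @param frame_metadata an `sfx_raw_frame` / `sfx_cal_frame`, or a list
#'   with a `photodiode` element.
#' @param threshold decision threshold on the normalized photodiode scale.
#' @return `"light"`, `"dark"` or `"n/a"`.
#' @export
classify_pump_state <- function(frame_metadata, threshold = 0.5) {
  pd <- frame_metadata$photodiode
  if (is.null(pd) || length(pd) == 0L || is.na(pd)) {
    warning("missing photodiode readout; pump state classified as n/a")
    return("n/a")
  }
  if (pd >= threshold) "light" else "dark"
}
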