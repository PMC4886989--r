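#' Calibration parameters
#'
#' Constants for the photon normalization.  A photon of energy E (eV)
#' liberates `E / 3.65` electron-hole pairs in the sensor silicon; the
#' per-module gain converts ADU to electrons.  Calibrated images are kept
#' in "deci-photon" units: ten units correspond to one photon, which
#' preserves sub-photon noise structure in a 16-bit integer.  The pair
#' energy (3.65 eV) and the units-per-photon scale (10) are physical /
#' format constants and are not configurable.
#'
#' @param gains per-module electrons-per-ADU values.
#' @param photon_energy_ev beam photon energy in eV.
#' @return an object of class `sfx_cal_params`.
#' @export
calibration_params <- function(gains = rep(1.0, 8L),
                               photon_energy_ev = 7300) {
  stopifnot(all(gains > 0), photon_energy_ev > 0)
  structure(list(gains = as.numeric(gains),
                 photon_energy_ev = photon_energy_ev,
                 pair_energy_ev = 3.65,
                 units_per_photon = 10L),
            class = "sfx_cal_params")
}

#' Build the dark reference
#'
#' Per-pixel arithmetic mean of the run's shutter-closed frames.  Accepts
#' either an [synthetic_run()] (its dark block is used) or a list of raw
#' frames; any shutter-open frame in the input is an error (the dark block
#' must not be mixed with exposed frames).
#'
#' @param x an `sfx_run` or a list of `sfx_raw_frame`s.
#' @param run_id run identifier recorded in the reference (taken from the
#'   run when `x` is an `sfx_run`).
#' @return an object of class `sfx_dark`: per-module mean matrices
#'   (`$panels`, double), `$n_frames_used`, `$run_id`.
#' @export
compute_dark <- function(x, run_id = NA_integer_) {
  if (inherits(x, "sfx_run")) {
    run_id <- x$manifest$run_id
    frames <- lapply(seq_len(x$manifest$n_dark), function(i) get_frame(x, i))
  } else {
    frames <- x
  }
  if (length(frames) == 0L) stop("at least one dark frame is required")
  if (any(vapply(frames, function(f) isTRUE(f$shutter_open), logical(1))))
    stop("dark block contains shutter-open frames")
  acc <- lapply(frames[[1]]$panels, function(p) {
    q <- p; storage.mode(q) <- "double"; q
  })
  for (f in frames[-1])
    for (m in seq_along(acc)) acc[[m]] <- acc[[m]] + f$panels[[m]]
  n <- length(frames)
  structure(list(panels = lapply(acc, function(p) p / n),
                 n_frames_used = n,
                 run_id = run_id),
            class = "sfx_dark")
}

#' Calibrate a raw frame to deci-photon units
#'
#' Applies the photon normalization per pixel:
#' `value = round((ADU - dark) * gain * 3.65 / photon_energy * 10)`,
#' with the module's gain applied to its panel, rounding half away from
#' zero, and clipping to the symmetric signed 16-bit range (plus/minus
#' 32767; values are clipped, never wrapped).  Negative values from noise
#' are preserved -- they carry the pedestal statistics needed for SNR
#' estimation downstream.  This normalization makes spot-finding
#' thresholds insensitive to the photon energy.
#'
#' @param raw an `sfx_raw_frame` with `shutter_open = TRUE`.
#' @param dark an [compute_dark()] reference of matching shape.
#' @param params an [calibration_params()]; `photon_energy_ev` defaults to
#'   the frame's own metadata when constructed via [pipeline_config()].
#' @return an `sfx_cal_frame`: 8 integer panel matrices in deci-photon
#'   units plus carried metadata.
#' @examples
#' # one photon at 7300 eV deposits 2000 electrons: with unit gain,
#' # ADU - dark = 2000 calibrates to exactly 10 units
#' raw <- structure(list(tag = 1, panels = list(matrix(2200L, 2, 2)),
#'                       shutter_open = TRUE, photon_energy_ev = 7300,
#'                       photodiode = 0, spectrum_mean_ev = 7300),
#'                  class = "sfx_raw_frame")
#' dark <- structure(list(panels = list(matrix(200, 2, 2)),
#'                        n_frames_used = 1, run_id = 1),
#'                   class = "sfx_dark")
#' calibrate(raw, dark, calibration_params(gains = 1))$panels[[1]][1, 1]
#' @export
calibrate <- function(raw, dark, params = calibration_params()) {
  stopifnot(inherits(raw, "sfx_raw_frame"), inherits(dark, "sfx_dark"),
            inherits(params, "sfx_cal_params"))
  if (!isTRUE(raw$shutter_open))
    stop("refusing to calibrate a shutter-closed (dark) frame")
  if (length(raw$panels) != length(dark$panels))
    stop("panel count mismatch between frame and dark reference")
  gains <- params$gains
  if (length(gains) == 1L) gains <- rep(gains, length(raw$panels))
  scale <- gains * params$pair_energy_ev / params$photon_energy_ev *
    params$units_per_photon
  panels <- lapply(seq_along(raw$panels), function(m) {
    if (!all(dim(raw$panels[[m]]) == dim(dark$panels[[m]])))
      stop("panel shape mismatch between frame and dark reference")
    v <- round_half_away((raw$panels[[m]] - dark$panels[[m]]) * scale[m])
    v <- pmax(pmin(v, 32767), -32767)
    storage.mode(v) <- "integer"
    v
  })
  structure(list(tag = raw$tag, panels = panels,
                 photon_energy_ev = params$photon_energy_ev,
                 photodiode = raw$photodiode,
                 spectrum_mean_ev = raw$spectrum_mean_ev),
            class = "sfx_cal_frame")
}

#' Per-pixel photon estimate of a calibrated frame
#'
#' Deci-photon values divided by 10; negative noise values are preserved.
#'
#' @param frame an `sfx_cal_frame`.
#' @return list of double matrices, photons per pixel.
#' @export
photons <- function(frame) {
  stopifnot(inherits(frame, "sfx_cal_frame"))
  lapply(frame$panels, function(p) p / 10)
}

#' Deci-photon value corresponding to a raw saturation level
#'
#' Convenience for setting [spot_find_params()]`$saturation_value`
#' consistently with the calibration: the calibrated value a pixel clipped
#' at `saturation_adu` maps to.
#'
#' @param saturation_adu raw clip level (ADU).
#' @param pedestal_adu dark level subtracted from it.
#' @param gain electrons per ADU.
#' @param photon_energy_ev photon energy.
#' @return deci-photon value (numeric).
#' @export
saturation_deciphotons <- function(saturation_adu = 65000,
                                   pedestal_adu = 200, gain = 1,
                                   photon_energy_ev = 7300) {
  round_half_away((saturation_adu - pedestal_adu) * gain * 3.65 /
                    photon_energy_ev * 10)
}

#' Persist / load a dark reference as HDF5
#'
#' One dataset per module (`module-0` ...) plus `run_id` and
#' `n_frames_used` scalars.
#'
#' @param dark an `sfx_dark`.
#' @param path HDF5 file path.
#' @return `read_dark_h5` returns an `sfx_dark`.
#' @export
write_dark_h5 <- function(dark, path) {
  stopifnot(inherits(dark, "sfx_dark"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (m in seq_along(dark$panels))
    rhdf5::h5write(dark$panels[[m]], path, sprintf("module-%d", m - 1L))
  rhdf5::h5write(dark$n_frames_used, path, "n_frames_used")
  rhdf5::h5write(as.integer(dark$run_id), path, "run_id")
  invisible(path)
}

#' @rdname write_dark_h5
#' @export
read_dark_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  names <- rhdf5::h5ls(path, recursive = FALSE)$name
  mods <- sort(as.integer(sub("^module-", "",
                              grep("^module-[0-9]+$", names, value = TRUE))))
  panels <- lapply(mods, function(m)
    rhdf5::h5read(path, sprintf("module-%d", m)))
  structure(list(panels = panels,
                 n_frames_used = as.numeric(
                   rhdf5::h5read(path, "n_frames_used")),
                 run_id = as.integer(rhdf5::h5read(path, "run_id"))),
            class = "sfx_dark")
}
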