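#' Spot-finding parameters
#'
#' Controls the threshold / connected-components / filter pipeline of
#' [find_spots()].  All intensity values are in deci-photon units (10 =
#' one photon), so the same thresholds work across photon energies.
#'
#' @param pixel_threshold binarization threshold, deci-photons (default
#'   50, i.e. 5 photons); comparison is inclusive (`>=`).
#' @param connectivity 4 or 8 (default 8: diagonally touching strong
#'   pixels belong to one spot).
#' @param min_area,max_area accepted component size range in pixels.
#' @param min_snr minimum peak signal-to-noise ratio.
#' @param annulus_inner,annulus_outer background annulus margins, in
#'   pixels, around the component bounding box: pixels between the box
#'   grown by `annulus_inner` and by `annulus_outer` (above-threshold
#'   pixels excluded) estimate the local background and noise.
#' @param saturation_value deci-photon level at which a pixel counts as
#'   saturated (default: raw 65000 ADU clip level through the default
#'   calibration, see [saturation_deciphotons()]).
#' @return an object of class `sfx_spot_params`.
#' @export
spot_find_params <- function(pixel_threshold = 50,
                             connectivity = 8L,
                             min_area = 1L,
                             max_area = 100L,
                             min_snr = 5.0,
                             annulus_inner = 2L,
                             annulus_outer = 5L,
                             saturation_value = saturation_deciphotons()) {
  stopifnot(connectivity %in% c(4L, 8L), min_area >= 1L,
            min_area <= max_area, min_snr >= 0,
            annulus_inner >= 0L, annulus_inner < annulus_outer)
  structure(as.list(environment()), class = "sfx_spot_params")
}

#' Binarize a calibrated frame
#'
#' Per-panel mask of pixels at or above the threshold (inclusive).
#' Components never cross panel boundaries: each panel is binarized and
#' labeled independently.
#'
#' @param frame an `sfx_cal_frame`.
#' @param threshold deci-photon threshold.
#' @return list of logical matrices, one per panel.
#' @export
binarize <- function(frame, threshold) {
  stopifnot(inherits(frame, "sfx_cal_frame"))
  lapply(frame$panels, function(p) p >= threshold)
}

#' Label connected components of a binary mask
#'
#' Decomposes the strong pixels of one panel mask into maximal connected
#' regions under 4- or 8-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background) with attribute
#'   `n_components`.
#' @export
connected_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .label_components(mask, as.integer(connectivity))
}

# Background and noise from the annulus around a component bounding box.
# Returns c(background, noise, fallback_flag).
annulus_stats <- function(panel, mask, bbox, inner, outer) {
  nr <- nrow(panel); nc <- ncol(panel)
  r0 <- max(1L, bbox[1] - outer); r1 <- min(nr, bbox[2] + outer)
  c0 <- max(1L, bbox[3] - outer); c1 <- min(nc, bbox[4] + outer)
  ri0 <- bbox[1] - inner; ri1 <- bbox[2] + inner
  ci0 <- bbox[3] - inner; ci1 <- bbox[4] + inner
  rows <- r0:r1; cols <- c0:c1
  sub <- panel[rows, cols, drop = FALSE]
  msk <- mask[rows, cols, drop = FALSE]
  in_inner <- outer(rows >= ri0 & rows <= ri1, cols >= ci0 & cols <= ci1,
                    "&")
  keep <- !in_inner & !msk
  vals <- sub[keep]
  if (length(vals) == 0L) {  # annulus entirely outside / masked: fall back
    vals <- panel[!mask]
    if (length(vals) == 0L) vals <- as.numeric(panel)
    fallback <- TRUE
  } else fallback <- FALSE
  c(stats::median(vals), stats::mad(vals), as.numeric(fallback))
}

# Score one connected component.  `idx` = linear indices of the region.
score_region <- function(panel, mask, idx, params) {
  nr <- nrow(panel)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  bbox <- c(min(rows), max(rows), min(cols), max(cols))
  st <- annulus_stats(panel, mask, bbox,
                      params$annulus_inner, params$annulus_outer)
  background <- st[1]
  noise <- max(st[2], 1)  # floor of 1 deci-photon: no divide-by-zero
  vals <- panel[idx]
  peak <- max(vals)
  w <- pmax(vals - background, 0)
  if (sum(w) == 0) w <- rep(1, length(vals))
  list(area = length(idx),
       # centroid in 0-based pixel coordinates, intensity-weighted
       centroid_fast = sum((cols - 1L) * w) / sum(w),
       centroid_slow = sum((rows - 1L) * w) / sum(w),
       peak_value = peak,
       background = background,
       integrated_intensity = sum(vals - background),
       snr = (peak - background) / noise,
       is_saturated = any(vals >= params$saturation_value),
       background_fallback = st[3] > 0)
}

#' Find Bragg spot candidates in a calibrated frame
#'
#' The hit-finding spot search: binarize by threshold, decompose strong
#' pixels into connected components per panel, score each component
#' (intensity-weighted centroid, peak, background-subtracted integrated
#' intensity, SNR from the local annulus with MAD-based robust sigma and
#' a 1 deci-photon noise floor), then filter by area range and minimum
#' SNR.  Saturated accepted spots are counted for the monitor.
#'
#' @param frame an `sfx_cal_frame`.
#' @param params an [spot_find_params()].
#' @return an `sfx_spotlist`: `$spots` data.frame (0-based `fast`/`slow`
#'   centroids, `module`, `area`, `peak_value`, `intensity`, `snr`,
#'   `is_saturated`) of accepted candidates plus rejection counters
#'   `$n_rejected_area`, `$n_rejected_snr` and `$n_saturated`.
#' @export
find_spots <- function(frame, params = spot_find_params()) {
  stopifnot(inherits(frame, "sfx_cal_frame"),
            inherits(params, "sfx_spot_params"))
  masks <- binarize(frame, params$pixel_threshold)
  out <- list()
  n_rej_area <- 0L; n_rej_snr <- 0L
  for (m in seq_along(frame$panels)) {
    mask <- masks[[m]]
    if (!any(mask)) next
    lab <- connected_components(mask, params$connectivity)
    n <- attr(lab, "n_components")
    if (n == 0L) next
    regions <- split(which(lab > 0), lab[lab > 0])
    panel <- frame$panels[[m]]
    for (idx in regions) {
      area <- length(idx)
      if (area < params$min_area || area > params$max_area) {
        n_rej_area <- n_rej_area + 1L
        next
      }
      sc <- score_region(panel, mask, idx, params)
      if (sc$snr < params$min_snr) {
        n_rej_snr <- n_rej_snr + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        module = m - 1L, fast = sc$centroid_fast, slow = sc$centroid_slow,
        area = sc$area, peak_value = sc$peak_value,
        intensity = sc$integrated_intensity, snr = sc$snr,
        is_saturated = sc$is_saturated)
    }
  }
  spots <- if (length(out)) do.call(rbind, out) else
    data.frame(module = integer(0), fast = numeric(0), slow = numeric(0),
               area = integer(0), peak_value = numeric(0),
               intensity = numeric(0), snr = numeric(0),
               is_saturated = logical(0))
  structure(list(tag = frame$tag, spots = spots,
                 n_rejected_area = n_rej_area,
                 n_rejected_snr = n_rej_snr,
                 n_saturated = sum(spots$is_saturated)),
            class = "sfx_spotlist")
}

#' @export
print.sfx_spotlist <- function(x, ...) {
  cat(sprintf(
    "<sfx_spotlist> tag %.0f: %d accepted (%d saturated), rejected %d by area, %d by SNR\n",
    x$tag, nrow(x$spots), x$n_saturated, x$n_rejected_area,
    x$n_rejected_snr))
  invisible(x)
}

#' Write spot lists in a CrystFEL-stream-like text block
#'
#' One `Peaks from peak search` block per event with `fs/px`, `ss/px`,
#' `panel` and intensity columns, appended to `path`.
#'
#' @param spotlists list of `sfx_spotlist`s.
#' @param path output text file.
#' @export
write_peaks_stream <- function(spotlists, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sl in spotlists) {
    writeLines(c("----- Begin chunk -----",
                 sprintf("Event: tag-%.0f", sl$tag),
                 "Peaks from peak search",
                 "  fs/px   ss/px  intensity  panel"), con)
    s <- sl$spots
    if (nrow(s))
      writeLines(sprintf("%8.2f %8.2f %10.2f  p%d",
                         s$fast, s$slow, s$intensity, s$module), con)
    writeLines(c("End of peak list", "----- End chunk -----"), con)
  }
  invisible(path)
}
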