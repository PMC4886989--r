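#' Run manifest
#'
#' Describes one acquisition run.  A run is a contiguous block of frames
#' sharing one detector configuration: the first `n_dark` frames are dark
#' images collected with the shutter closed, followed by `n_exposed`
#' exposed images (150 + 5000 = 5150 frames in a standard run).  Every
#' XFEL pulse carries a unique 64-bit tag number; tags are consecutive
#' within a run and unique across runs.
#'
#' @param run_id integer run identifier.
#' @param n_dark number of shutter-closed frames at the start of the run.
#' @param n_exposed number of exposed frames following the dark block.
#' @param first_tag tag number of the first frame (stored as a double;
#'   exact for values below 2^53).
#' @param repetition_rate_hz nominal pulse repetition rate.
#' @param photon_energy_ev photon energy of the run.
#' @param pump_probe logical; if `TRUE` frames carry a pump-laser
#'   photodiode readout and alternate light/dark states.
#' @return an object of class `sfx_manifest`.
#' @export
run_manifest <- function(run_id = 1L,
                         n_dark = 150L,
                         n_exposed = 5000L,
                         first_tag = run_id * 1e7,
                         repetition_rate_hz = 30,
                         photon_energy_ev = 7300,
                         pump_probe = FALSE) {
  stopifnot(n_dark >= 1L, n_exposed >= 0L, photon_energy_ev > 0,
            repetition_rate_hz > 0)
  structure(list(run_id = as.integer(run_id),
                 n_dark = as.integer(n_dark),
                 n_exposed = as.integer(n_exposed),
                 first_tag = as.numeric(first_tag),
                 repetition_rate_hz = repetition_rate_hz,
                 photon_energy_ev = photon_energy_ev,
                 pump_probe = isTRUE(pump_probe)),
            class = "sfx_manifest")
}

#' Synthetic-beam simulation parameters
#'
#' The generative model behind [synthetic_run()].  Signals are simulated in
#' photons, converted to electrons (one photon makes
#' `photon_energy / 3.65` electron-hole pairs in silicon) and divided by
#' the per-module gain to obtain ADU, so that the calibration model inverts
#' the generator exactly in expectation.  Each exposed frame receives, on
#' top of a Gaussian pedestal, a carrier-medium scattering ring centered on
#' the beam axis and -- with probability `hit_fraction` -- a set of planted
#' Bragg spots with 2-D Gaussian profiles and Poisson photon statistics.
#' Pixels are clipped at `saturation_adu` before the integer cast; a spot
#' whose expected peak exceeds the clip level is flagged saturated in the
#' ground truth.
#'
#' Defaults (see the methods vignette for rationale): pedestal 200 ADU,
#' read noise 4 ADU, unit gain (so one 7300 eV photon = 2000 electrons =
#' 2000 ADU), saturation at 65000 ADU, 30% hit fraction, Poisson(40) spots
#' per hit with log-normal intensities (median 500 photons), spot sigma
#' 1.5 px, and a weak carrier ring (1 photon/pixel at the crest, radius
#' 600 px) emulating a well-attenuated experiment; strong-ring regimes
#' are exercised explicitly in tests by raising `ring_peak_photons`.
#'
#' @param pedestal_adu mean dark level, ADU.
#' @param read_noise_adu Gaussian read noise sigma, ADU.
#' @param hit_fraction probability that a shot intersects a crystal.
#' @param spots_per_hit_mean,spots_per_hit_dispersion negative-binomial
#'   mean and size for the number of spots in a hit; `Inf` size = Poisson.
#' @param spot_sigma_px isotropic 2-D Gaussian sigma of a spot, pixels.
#' @param spot_photons_meanlog,spot_photons_sdlog log-normal parameters of
#'   the integrated photons per spot (`sdlog = 0` gives a constant).
#' @param min_separation_px minimum center-to-center distance between
#'   planted spots on the same panel (0 disables the constraint).
#' @param ring_radius_px,ring_width_px,ring_peak_photons carrier-medium
#'   ring: radius and Gaussian radial width in pixels from the beam axis,
#'   and expected photons/pixel at the ring crest (0 disables the ring).
#' @param saturation_adu full-well clip level, ADU (at most 65535).
#' @param seed RNG seed for the whole run (frames are derived
#'   deterministically from it; same seed, same bytes).
#' @return an object of class `sfx_sim_params`.
#' @export
sim_params <- function(pedestal_adu = 200,
                       read_noise_adu = 4,
                       hit_fraction = 0.3,
                       spots_per_hit_mean = 40,
                       spots_per_hit_dispersion = Inf,
                       spot_sigma_px = 1.5,
                       spot_photons_meanlog = log(500),
                       spot_photons_sdlog = 0.75,
                       min_separation_px = 10,
                       ring_radius_px = 600,
                       ring_width_px = 20,
                       ring_peak_photons = 1,
                       saturation_adu = 65000,
                       seed = 1L) {
  stopifnot(pedestal_adu >= 0, read_noise_adu >= 0,
            hit_fraction >= 0, hit_fraction <= 1,
            spots_per_hit_mean >= 0, spot_sigma_px > 0,
            min_separation_px >= 0, ring_radius_px >= 0, ring_width_px >= 0,
            ring_peak_photons >= 0,
            saturation_adu > 0, saturation_adu <= 65535)
  structure(as.list(environment()), class = "sfx_sim_params")
}

gaussian_footprint <- function(center_fast, center_slow, sigma,
                               fast_extent, slow_extent) {
  w <- ceiling(4 * sigma)
  f0 <- max(0, floor(center_fast) - w)
  f1 <- min(fast_extent - 1L, floor(center_fast) + w + 1L)
  s0 <- max(0, floor(center_slow) - w)
  s1 <- min(slow_extent - 1L, floor(center_slow) + w + 1L)
  ff <- f0:f1
  ss <- s0:s1
  g <- exp(-outer((ss - center_slow)^2, (ff - center_fast)^2, "+") /
             (2 * sigma^2))
  list(fast = ff, slow = ss, weights = g / sum(g))
}

ring_support <- function(geometry, params) {
  if (params$ring_peak_photons <= 0) return(NULL)
  bx <- geometry$beam_center_mm[1]
  by <- geometry$beam_center_mm[2]
  lapply(geometry$panels, function(p) {
    f <- seq_len(p$fast_extent) - 1L
    s <- seq_len(p$slow_extent) - 1L
    x <- p$origin_lab[1] + outer(s * p$slow_axis[1], f * p$fast_axis[1],
                                 "+") * p$pixel_size
    y <- p$origin_lab[2] + outer(s * p$slow_axis[2], f * p$fast_axis[2],
                                 "+") * p$pixel_size
    r_px <- sqrt((x - bx)^2 + (y - by)^2) / p$pixel_size
    lam <- params$ring_peak_photons *
      exp(-(r_px - params$ring_radius_px)^2 / (2 * params$ring_width_px^2))
    idx <- which(lam > 0.01)
    if (length(idx) == 0L) NULL else list(idx = idx, lambda = lam[idx])
  })
}

sample_spot_positions <- function(n, geometry, params) {
  sigma <- params$spot_sigma_px
  margin <- 2 * sigma
  modules <- sample.int(geometry$n_modules, n, replace = TRUE) - 1L
  fast <- numeric(n); slow <- numeric(n)
  for (k in seq_len(n)) {
    p <- geometry$panels[[modules[k] + 1L]]
    for (try in 1:50) {
      f <- stats::runif(1, margin, p$fast_extent - 1 - margin)
      s <- stats::runif(1, margin, p$slow_extent - 1 - margin)
      same <- which(modules[seq_len(k - 1L)] == modules[k])
      if (params$min_separation_px == 0 || length(same) == 0L ||
          min(sqrt((fast[same] - f)^2 + (slow[same] - s)^2)) >=
            params$min_separation_px) break
    }
    fast[k] <- f; slow[k] <- s
  }
  data.frame(module = modules, fast = fast, slow = slow)
}

#' Generate a synthetic run with ground truth
#'
#' Builds a deterministic synthetic run: `n_dark` shutter-closed pedestal
#' frames followed by `n_exposed` frames carrying ring background and, for
#' hits, planted Bragg spots.  All random choices derive from
#' `params$seed`, so the same inputs reproduce bit-identical frames and
#' ground truth.  Frames are rendered lazily by [get_frame()]; the ground
#' truth (one row per frame in `$truth$frames`, one row per planted spot
#' in `$truth$spots`) is materialized immediately and is the oracle for
#' all detection tests.
#'
#' @param manifest a [run_manifest()].
#' @param params a [sim_params()].
#' @param geometry a [detector_geometry()].
#' @return an object of class `sfx_run` with elements `manifest`,
#'   `params`, `geometry`, `tags` and `truth`.
#' @examples
#' run <- synthetic_run(run_manifest(n_dark = 5, n_exposed = 10),
#'                      sim_params(seed = 7), mini_geometry())
#' n_frames(run)
#' head(run$truth$frames)
#' @export
synthetic_run <- function(manifest = run_manifest(),
                          params = sim_params(),
                          geometry = detector_geometry()) {
  stopifnot(inherits(manifest, "sfx_manifest"),
            inherits(params, "sfx_sim_params"))
  assert_geometry(geometry)
  if (params$hit_fraction > 0 && params$spots_per_hit_mean == 0)
    stop("spots_per_hit_mean must be positive when hit_fraction > 0")
  n_total <- manifest$n_dark + manifest$n_exposed
  tags <- manifest$first_tag + seq_len(n_total) - 1
  exposed <- seq_len(n_total) > manifest$n_dark
  epe <- manifest$photon_energy_ev / 3.65  # electrons per photon

  truth <- with_seed(frame_seed(params$seed, 0L), {
    pump_state <- rep("n/a", n_total)
    photodiode <- rep(0, n_total)
    if (manifest$pump_probe && manifest$n_exposed > 0) {
      sched <- pump_probe_schedule(manifest)
      pump_state[exposed] <- sched$pump_state
      photodiode[exposed] <- sched$photodiode
    }
    is_hit <- logical(n_total)
    if (manifest$n_exposed > 0)
      is_hit[exposed] <- stats::runif(manifest$n_exposed) < params$hit_fraction
    n_spots <- integer(n_total)
    hit_idx <- which(is_hit)
    if (length(hit_idx) > 0) {
      draw <- if (is.infinite(params$spots_per_hit_dispersion))
        stats::rpois(length(hit_idx), params$spots_per_hit_mean)
      else
        stats::rnbinom(length(hit_idx), mu = params$spots_per_hit_mean,
                       size = params$spots_per_hit_dispersion)
      n_spots[hit_idx] <- pmax(1L, draw)  # a hit has at least one spot
    }
    spots <- vector("list", length(hit_idx))
    for (j in seq_along(hit_idx)) {
      i <- hit_idx[j]
      ns <- n_spots[i]
      pos <- sample_spot_positions(ns, geometry, params)
      photons <- if (params$spot_photons_sdlog == 0)
        rep(exp(params$spot_photons_meanlog), ns)
      else stats::rlnorm(ns, params$spot_photons_meanlog,
                         params$spot_photons_sdlog)
      peak_frac <- vapply(seq_len(ns), function(k) {
        p <- geometry$panels[[pos$module[k] + 1L]]
        max(gaussian_footprint(pos$fast[k], pos$slow[k],
                               params$spot_sigma_px,
                               p$fast_extent, p$slow_extent)$weights)
      }, numeric(1))
      gains <- geometry$gains[pos$module + 1L]
      peak_adu <- params$pedestal_adu + photons * peak_frac * epe / gains
      spots[[j]] <- data.frame(
        tag = tags[i], frame_index = i, module = pos$module,
        fast = pos$fast, slow = pos$slow, photons = photons,
        is_saturated = peak_adu >= params$saturation_adu)
    }
    list(frames = data.frame(
           tag = tags, frame_index = seq_len(n_total),
           shutter_open = exposed, is_hit = is_hit, n_spots = n_spots,
           has_ring = exposed & params$ring_peak_photons > 0,
           pump_state = pump_state, photodiode = photodiode),
         spots = if (length(spots)) do.call(rbind, spots) else
           data.frame(tag = numeric(0), frame_index = integer(0),
                      module = integer(0), fast = numeric(0),
                      slow = numeric(0), photons = numeric(0),
                      is_saturated = logical(0)))
  })

  structure(list(manifest = manifest, params = params, geometry = geometry,
                 tags = tags, truth = truth,
                 ring = ring_support(geometry, params)),
            class = "sfx_run")
}

#' @rdname synthetic_run
#' @export
generate_run <- synthetic_run

#' @export
print.sfx_run <- function(x, ...) {
  cat(sprintf(
    "<sfx_run> run %d: %d dark + %d exposed frames, %d ground-truth hits\n",
    x$manifest$run_id, x$manifest$n_dark, x$manifest$n_exposed,
    sum(x$truth$frames$is_hit)))
  invisible(x)
}

#' Number of frames in a run
#' @param run an `sfx_run`.
#' @return integer frame count (dark + exposed).
#' @export
n_frames <- function(run) run$manifest$n_dark + run$manifest$n_exposed

#' Render one raw frame of a synthetic run
#'
#' Deterministically renders frame `i` (1-based; dark block first).  The
#' pixel model is `ADU = pedestal + N(0, read_noise) + signal/gain`, with
#' signal photons Poisson-sampled from the ring and planted-spot intensity
#' surfaces, clipped to `[0, saturation_adu]` and rounded to unsigned
#' 16-bit integers.
#'
#' @param run an [synthetic_run()] object.
#' @param i frame index, 1 to `n_frames(run)`.
#' @return an `sfx_raw_frame`: list with `tag`, `panels` (8 integer
#'   matrices, slow x fast), `shutter_open`, `photon_energy_ev`,
#'   `photodiode`, `spectrum_mean_ev`.
#' @export
get_frame <- function(run, i) {
  stopifnot(inherits(run, "sfx_run"), i >= 1, i <= n_frames(run))
  i <- as.integer(i)
  m <- run$manifest; pr <- run$params; geom <- run$geometry
  info <- run$truth$frames[i, ]
  epe <- m$photon_energy_ev / 3.65
  with_seed(frame_seed(pr$seed, i), {
    panels <- lapply(geom$panels, function(p) {
      n <- p$fast_extent * p$slow_extent
      matrix(pr$pedestal_adu + stats::rnorm(n, sd = pr$read_noise_adu),
             nrow = p$slow_extent, ncol = p$fast_extent)
    })
    if (info$shutter_open) {
      if (!is.null(run$ring)) {
        for (mm in seq_along(panels)) {
          sup <- run$ring[[mm]]
          if (is.null(sup)) next
          counts <- stats::rpois(length(sup$lambda), sup$lambda)
          panels[[mm]][sup$idx] <- panels[[mm]][sup$idx] +
            counts * epe / geom$gains[mm]
        }
      }
      sp <- run$truth$spots
      sp <- sp[sp$frame_index == i, , drop = FALSE]
      for (k in seq_len(nrow(sp))) {
        mm <- sp$module[k] + 1L
        p <- geom$panels[[mm]]
        fp <- gaussian_footprint(sp$fast[k], sp$slow[k], pr$spot_sigma_px,
                                 p$fast_extent, p$slow_extent)
        counts <- stats::rpois(length(fp$weights),
                               sp$photons[k] * fp$weights)
        panels[[mm]][fp$slow + 1L, fp$fast + 1L] <-
          panels[[mm]][fp$slow + 1L, fp$fast + 1L] +
          matrix(counts, nrow = length(fp$slow)) * epe / geom$gains[mm]
      }
    }
    panels <- lapply(panels, function(x) {
      x <- round_half_away(pmax(pmin(x, pr$saturation_adu), 0))
      storage.mode(x) <- "integer"
      x
    })
    spectrum_mean <- m$photon_energy_ev + stats::rnorm(1, sd = 1)
    structure(list(tag = info$tag,
                   panels = panels,
                   shutter_open = info$shutter_open,
                   photon_energy_ev = m$photon_energy_ev,
                   photodiode = info$photodiode,
                   spectrum_mean_ev = spectrum_mean),
              class = "sfx_raw_frame")
  })
}

#' Pump-probe light/dark schedule
#'
#' Assigns a pump-laser state to every exposed frame of a run and draws a
#' photodiode readout from well-separated distributions (light: N(1, 0.05);
#' dark: N(0, 0.02)), on a normalized scale where 0.5 cleanly splits the
#' two.  The default pattern alternates light and dark shots; passing
#' `p_light` instead draws states independently at random.
#'
#' @param manifest a [run_manifest()] with `pump_probe = TRUE`.
#' @param pattern character vector of states recycled over exposed frames
#'   (default alternation `c("light", "dark")`).
#' @param p_light if non-`NULL`, probability of a light shot; overrides
#'   `pattern`.
#' @return data.frame with `tag`, `pump_state`, `photodiode`, one row per
#'   exposed frame.  Uses the current RNG stream.
#' @export
pump_probe_schedule <- function(manifest, pattern = c("light", "dark"),
                                p_light = NULL) {
  if (!isTRUE(manifest$pump_probe))
    stop("manifest does not have the pump_probe flag set")
  if (is.null(p_light) && length(pattern) == 0)
    stop("pattern must contain at least one state")
  n <- manifest$n_exposed
  tags <- manifest$first_tag + manifest$n_dark + seq_len(n) - 1
  state <- if (!is.null(p_light)) {
    stopifnot(p_light >= 0, p_light <= 1)
    ifelse(stats::runif(n) < p_light, "light", "dark")
  } else {
    rep_len(pattern, n)
  }
  photodiode <- ifelse(state == "light",
                       stats::rnorm(n, 1, 0.05),
                       stats::rnorm(n, 0, 0.02))
  data.frame(tag = tags, pump_state = state, photodiode = photodiode)
}

#' Write ground truth as TSV
#'
#' Per-frame table: `tag`, `is_hit`, `n_spots`, `pump_state`.
#'
#' @param run an `sfx_run`.
#' @param path output file.
#' @export
write_truth_tsv <- function(run, path) {
  fr <- run$truth$frames
  utils::write.table(
    data.frame(tag = sprintf("%.0f", fr$tag), is_hit = fr$is_hit,
               n_spots = fr$n_spots, pump_state = fr$pump_state),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
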