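#' Match found spots against planted ground truth
#'
#' Greedy nearest-neighbour one-to-one matching within a pixel radius, on
#' the same panel.  Pairs are considered in order of increasing centroid
#' distance; each found spot and each true spot is used at most once.
#' The paper-scale objective for parameter choice is the indexing rate,
#' which needs external indexing software; against synthetic ground truth
#' the spot-recovery F1 is the desk-scale stand-in.
#'
#' Conventions for empty sets: recall is 1 when there are no true spots,
#' precision is 1 when nothing was found; so an empty frame scores (1,1,1)
#' and a miss on a non-empty frame scores recall 0.
#'
#' @param found an `sfx_spotlist` or its `$spots` data.frame.
#' @param truth data.frame of planted spots for the same frame (columns
#'   `module`, `fast`, `slow`).
#' @param radius match radius in pixels (default 2).
#' @return list: `recall`, `precision`, `f1`, `n_matched`, `n_found`,
#'   `n_truth`.
#' @export
match_spots <- function(found, truth, radius = 2) {
  f <- if (inherits(found, "sfx_spotlist")) found$spots else found
  nf <- nrow(f); nt <- nrow(truth)
  n_matched <- 0L
  if (nf > 0 && nt > 0) {
    pairs <- NULL
    for (m in intersect(unique(f$module), unique(truth$module))) {
      fi <- which(f$module == m); ti <- which(truth$module == m)
      d <- sqrt(outer(f$fast[fi], truth$fast[ti], "-")^2 +
                  outer(f$slow[fi], truth$slow[ti], "-")^2)
      ok <- which(d <= radius, arr.ind = TRUE)
      if (nrow(ok))
        pairs <- rbind(pairs, cbind(fi[ok[, 1]], ti[ok[, 2]],
                                    d[ok]))
    }
    if (!is.null(pairs)) {
      pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
      used_f <- logical(nf); used_t <- logical(nt)
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        if (!used_f[a] && !used_t[b]) {
          used_f[a] <- TRUE; used_t[b] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  recall <- if (nt == 0) 1 else n_matched / nt
  precision <- if (nf == 0) 1 else n_matched / nf
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(recall = recall, precision = precision, f1 = f1,
       n_matched = n_matched, n_found = nf, n_truth = nt)
}

#' Parameter grid
#'
#' Named axes over [spot_find_params()] fields (`pixel_threshold`,
#' `min_snr`, `min_area`) or beam-center offsets (`beam_dx`, `beam_dy`,
#' in pixels), evaluated on a frame subset.
#'
#' @param ... named axes, each a vector of values.
#' @param n_eval number of exposed frames used for evaluation (default
#'   500, capped at the run size).
#' @return an `sfx_param_grid`.
#' @export
param_grid <- function(..., n_eval = 500L) {
  axes <- list(...)
  if (length(axes) == 1L && is.list(axes[[1]]) && is.null(names(axes)[1]))
    axes <- axes[[1]]
  if (length(axes) == 0L || is.null(names(axes)) || any(names(axes) == ""))
    stop("param_grid needs at least one named axis")
  known <- c("pixel_threshold", "min_snr", "min_area", "beam_dx", "beam_dy")
  bad <- setdiff(names(axes), known)
  if (length(bad)) stop("unknown grid axes: ", paste(bad, collapse = ", "))
  structure(list(axes = axes, n_eval = as.integer(n_eval)),
            class = "sfx_param_grid")
}

#' Grid search over spot-finding parameters
#'
#' Exhaustively evaluates every cell of the grid on a subset of exposed
#' frames, scoring spot recovery (micro-averaged recall, precision, F1
#' over planted ground-truth spots) and the mean accepted spots per frame.
#' The best cell maximizes `objective`; ties break toward the smallest
#' `pixel_threshold`, then the smallest `min_snr` (permissive hit-finding
#' criteria: modest false positives are cheaper than discarded patterns).
#' Deterministic given the run and grid: the evaluation subset is the
#' first `n_eval` exposed frames.
#'
#' Beam-center axes (`beam_dx`/`beam_dy`) cannot be scored by F1 --
#' planted spot positions are panel-local -- and are handled by
#' [scan_beam_center()] instead.
#'
#' @param run an [synthetic_run()] (its ground truth is the oracle).
#' @param grid an [param_grid()].
#' @param objective `"f1"`, `"recall"` or `"precision"`.
#' @param spot_params base [spot_find_params()] the axes override.
#' @param match_radius pixel radius for [match_spots()].
#' @return an `sfx_grid_result`: `$table` (one row per cell with metrics)
#'   and `$best` (the selected row).
#' @export
grid_search <- function(run, grid, objective = c("f1", "recall",
                                                 "precision"),
                        spot_params = spot_find_params(),
                        match_radius = 2) {
  objective <- match.arg(objective)
  stopifnot(inherits(run, "sfx_run"), inherits(grid, "sfx_param_grid"))
  if (any(c("beam_dx", "beam_dy") %in% names(grid$axes)))
    stop("beam-center axes are scanned with scan_beam_center()")
  n_eval <- min(grid$n_eval, run$manifest$n_exposed)
  if (n_eval < 1L) stop("no exposed frames to evaluate on")
  dark <- compute_dark(run)
  cal_par <- calibration_params(gains = run$geometry$gains,
                                photon_energy_ev =
                                  run$manifest$photon_energy_ev)
  idx <- run$manifest$n_dark + seq_len(n_eval)
  cal_frames <- lapply(idx, function(i)
    calibrate(get_frame(run, i), dark, cal_par))
  truth_by_frame <- lapply(idx, function(i) {
    sp <- run$truth$spots
    sp[sp$frame_index == i, , drop = FALSE]
  })

  cells <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    p <- spot_params
    for (ax in names(cells)) p[[ax]] <- cells[ci, ax]
    tm <- 0L; tt <- 0L; tf <- 0L
    for (k in seq_along(cal_frames)) {
      mt <- match_spots(find_spots(cal_frames[[k]], p),
                        truth_by_frame[[k]], match_radius)
      tm <- tm + mt$n_matched; tt <- tt + mt$n_truth; tf <- tf + mt$n_found
    }
    recall <- if (tt == 0) 1 else tm / tt
    precision <- if (tf == 0) 1 else tm / tf
    f1 <- if (recall + precision == 0) 0 else
      2 * recall * precision / (recall + precision)
    cbind(cells[ci, , drop = FALSE],
          data.frame(recall = recall, precision = precision, f1 = f1,
                     mean_spots_per_frame = tf / length(cal_frames)))
  })
  table <- do.call(rbind, res)
  rownames(table) <- NULL
  ord <- order(-table[[objective]],
               if ("pixel_threshold" %in% names(table))
                 table$pixel_threshold else rep(0, nrow(table)),
               if ("min_snr" %in% names(table)) table$min_snr else
                 rep(0, nrow(table)))
  structure(list(table = table, best = table[ord[1], , drop = FALSE],
                 objective = objective),
            class = "sfx_grid_result")
}

#' @export
print.sfx_grid_result <- function(x, ...) {
  cat(sprintf("<sfx_grid_result> %d cells, objective = %s\n",
              nrow(x$table), x$objective))
  cat("best cell:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Emit the chosen parameters as a pipeline config snippet
#'
#' YAML fragment with the best cell's parameter overrides, the analogue
#' of overriding downstream-processing arguments from a tuning run.
#'
#' @param result an `sfx_grid_result`.
#' @param path output file (YAML).
#' @export
write_best_params <- function(result, path) {
  stopifnot(inherits(result, "sfx_grid_result"))
  keep <- setdiff(names(result$best),
                  c("recall", "precision", "f1", "mean_spots_per_frame"))
  yaml::write_yaml(as.list(result$best[1, keep, drop = FALSE]), path)
  invisible(path)
}

#' Scan beam-center offsets against ring concentricity
#'
#' An error in the assumed beam center de-centers the carrier-medium
#' ring: the radial distances of strong ring pixels from the assumed
#' center spread out.  For each candidate offset (in pixels) the spread
#' (MAD of radii of above-threshold pixels, pooled over frames) is
#' computed; the offset minimizing the spread recovers a planted
#' beam-center error to within one grid step.  This is the desk-scale
#' analogue of refining the beam center before indexing.
#'
#' @param run an [synthetic_run()] whose frames carry a ring.
#' @param offsets_x,offsets_y candidate offsets in pixels (added to the
#'   geometry's beam center).
#' @param n_eval number of exposed frames pooled.
#' @param threshold deci-photon threshold selecting ring pixels.
#' @return data.frame `beam_dx`, `beam_dy`, `spread`; attribute `best` =
#'   the minimizing row.
#' @export
scan_beam_center <- function(run, offsets_x = -3:3, offsets_y = -3:3,
                             n_eval = 10L, threshold = 50) {
  stopifnot(inherits(run, "sfx_run"))
  geom <- run$geometry
  dark <- compute_dark(run)
  cal_par <- calibration_params(gains = geom$gains,
                                photon_energy_ev =
                                  run$manifest$photon_energy_ev)
  n_eval <- min(n_eval, run$manifest$n_exposed)
  idx <- run$manifest$n_dark + seq_len(n_eval)
  # lab-frame coordinates (in pixel units) of every strong pixel
  xs <- NULL; ys <- NULL
  for (i in idx) {
    cal <- calibrate(get_frame(run, i), dark, cal_par)
    for (m in seq_along(cal$panels)) {
      p <- geom$panels[[m]]
      w <- which(cal$panels[[m]] >= threshold, arr.ind = TRUE)
      if (nrow(w) == 0L) next
      s <- w[, 1] - 1L; f <- w[, 2] - 1L
      xs <- c(xs, (p$origin_lab[1] + (f * p$fast_axis[1] +
                s * p$slow_axis[1]) * p$pixel_size) / p$pixel_size)
      ys <- c(ys, (p$origin_lab[2] + (f * p$fast_axis[2] +
                s * p$slow_axis[2]) * p$pixel_size) / p$pixel_size)
    }
  }
  if (is.null(xs)) stop("no pixels above threshold; cannot scan")
  bx <- geom$beam_center_mm[1] / geom$panels[[1]]$pixel_size
  by <- geom$beam_center_mm[2] / geom$panels[[1]]$pixel_size
  cells <- expand.grid(beam_dx = offsets_x, beam_dy = offsets_y)
  cells$spread <- vapply(seq_len(nrow(cells)), function(ci) {
    r <- sqrt((xs - bx - cells$beam_dx[ci])^2 +
                (ys - by - cells$beam_dy[ci])^2)
    # mean absolute deviation about the median: smooth in the offset
    # (unlike the MAD, which plateaus on the bimodal radius distribution
    # of two short arcs) while still tolerating a few outlier pixels
    mean(abs(r - stats::median(r)))
  }, numeric(1))
  best <- cells[which.min(cells$spread), ]
  attr(cells, "best") <- best
  cells
}
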