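#' Named deterministic fixtures
#'
#' Seeded run definitions used by the examples, the tutorial and the test
#' suite.  Regenerating a fixture from its definition always reproduces
#' its expected summary exactly.
#'
#' * `"mini-run"`: 15 dark + 200 exposed frames on the scaled-down
#'   [mini_geometry()] (fast everywhere; the ring radius is scaled to the
#'   small array).
#' * `"standard-run"`: full-scale layout, 150 dark + 5000 exposed = 5150
#'   frames.  Only the manifest, ground truth and summary are written --
#'   frames are rendered on demand.
#' * `"pump-probe-run"`: mini-scale with alternating light/dark states.
#'
#' @param name fixture name.
#' @return list with `manifest`, `params`, `geometry` and the fixture
#'   `name`.
#' @export
fixture_definition <- function(name) {
  switch(name,
    "mini-run" = list(
      name = name,
      manifest = run_manifest(run_id = 101L, n_dark = 15L,
                              n_exposed = 200L),
      params = sim_params(ring_radius_px = 150, ring_width_px = 8,
                          seed = 42L),
      geometry = mini_geometry()),
    "standard-run" = list(
      name = name,
      manifest = run_manifest(run_id = 102L),
      params = sim_params(seed = 42L),
      geometry = detector_geometry()),
    "pump-probe-run" = list(
      name = name,
      manifest = run_manifest(run_id = 103L, n_dark = 15L,
                              n_exposed = 200L, pump_probe = TRUE),
      params = sim_params(ring_radius_px = 150, ring_width_px = 8,
                          seed = 42L),
      geometry = mini_geometry()),
    stop("unknown fixture '", name, "'; available: mini-run, ",
         "standard-run, pump-probe-run"))
}

#' Materialize a fixture on disk
#'
#' Generates the fixture run deterministically and writes `manifest.yaml`,
#' `geometry.geom`, `truth.tsv` and `expected_summary.yaml` (frame / hit
#' counts and a tag-sum checksum) under `dir/name/`.  For the mini-scale
#' fixtures the raw frames are also exported as `raw.h5`.
#'
#' @param name fixture name (see [fixture_definition()]).
#' @param dir parent output directory.
#' @param write_frames override the default choice of whether to write
#'   the raw-frame HDF5 file.
#' @return list with the generated `run` and the `paths` written.
#' @export
make_fixture <- function(name, dir = tempfile("fixtures"),
                         write_frames = NULL) {
  def <- fixture_definition(name)
  run <- synthetic_run(def$manifest, def$params, def$geometry)
  out <- file.path(dir, name)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    manifest = file.path(out, "manifest.yaml"),
    geometry = file.path(out, "geometry.geom"),
    truth = file.path(out, "truth.tsv"),
    summary = file.path(out, "expected_summary.yaml"))
  yaml::write_yaml(unclass(def$manifest), paths$manifest)
  write_geom_file(def$geometry, paths$geometry)
  write_truth_tsv(run, paths$truth)
  fr <- run$truth$frames
  yaml::write_yaml(list(
    name = name,
    n_frames = nrow(fr),
    n_dark = def$manifest$n_dark,
    n_hits = sum(fr$is_hit),
    n_light = sum(fr$pump_state == "light"),
    n_dark_state = sum(fr$pump_state == "dark"),
    tag_checksum = sprintf("%.0f", sum(run$tags)),
    seed = def$params$seed), paths$summary)
  write_frames <- write_frames %||% (name != "standard-run")
  if (write_frames) {
    paths$raw <- file.path(out, "raw.h5")
    write_raw_run(run, paths$raw)
  }
  list(run = run, paths = paths)
}
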