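#' Multi-module detector geometry
#'
#' An SFX-style multi-port CCD detector is read out as eight sensor modules
#' of 512 (fast) x 1024 (slow) pixels each.  In memory the eight panels are
#' stacked along the slow axis into a single 8192 x 512 array; this layout
#' carries no information about the physical arrangement (metrology) of the
#' modules, which is described separately by this geometry object and
#' exported as a CrystFEL-style `.geom` file for downstream tools.
#'
#' Conventions used throughout the package (documented, and asserted in the
#' test suite):
#' * the stacked array is `(rows, cols) = (n_modules * slow_extent,
#'   fast_extent)`, i.e. rows run along the stacking (slow) dimension;
#' * pixel indices `(fast, slow)` are 0-based with pixel centers at integer
#'   coordinates;
#' * panel matrices are stored as `slow_extent x fast_extent` R matrices
#'   (row = slow, column = fast).
#'
#' @param n_modules number of sensor modules (8 for the real detector).
#' @param fast_extent,slow_extent per-module extents in pixels.  Defaults
#'   match the real sensor (512 x 1024); scaled-down values are used for
#'   fast tests (see [mini_geometry()]).
#' @param pixel_size_mm pixel pitch in mm.
#' @param camera_length_mm sample-to-detector distance in mm.
#' @param beam_center_mm lab-frame (x, y) of the beam axis in mm.  The
#'   default metrology places the modules contiguously (no gaps) with the
#'   array center on the beam axis.
#' @param gains per-module detector gain in electrons per ADU (the
#'   sensor-specific constant measured by the detector team).
#' @return an object of class `sfx_geometry`.
#' @examples
#' geom <- detector_geometry()
#' stacked_shape(geom)          # c(8192, 512)
#' pixel_to_lab(geom, module = 0, fast = 0, slow = 0)
#' @export
detector_geometry <- function(n_modules = 8L,
                              fast_extent = 512L,
                              slow_extent = 1024L,
                              pixel_size_mm = 0.05,
                              camera_length_mm = 50,
                              beam_center_mm = c(0, 0),
                              gains = rep(1.0, n_modules)) {
  n_modules <- as.integer(n_modules)
  if (length(gains) == 1L) gains <- rep(gains, n_modules)
  stopifnot(n_modules >= 1L, fast_extent >= 1L, slow_extent >= 1L,
            pixel_size_mm > 0, camera_length_mm > 0,
            length(beam_center_mm) == 2L,
            length(gains) == n_modules, all(gains > 0))
  # Default metrology: contiguous vertical stack, beam at the array center.
  gs_center <- n_modules * slow_extent / 2
  fs_center <- fast_extent / 2
  panels <- lapply(seq_len(n_modules) - 1L, function(m) {
    list(index = m,
         fast_extent = as.integer(fast_extent),
         slow_extent = as.integer(slow_extent),
         origin_lab = c(beam_center_mm[1] - fs_center * pixel_size_mm,
                        beam_center_mm[2] + (m * slow_extent - gs_center) *
                          pixel_size_mm),
         fast_axis = c(1, 0),
         slow_axis = c(0, 1),
         pixel_size = pixel_size_mm)
  })
  structure(list(panels = panels,
                 n_modules = n_modules,
                 camera_length_mm = camera_length_mm,
                 beam_center_mm = as.numeric(beam_center_mm),
                 gains = as.numeric(gains)),
            class = "sfx_geometry")
}

#' Scaled-down geometry for fast tests
#'
#' Eight modules of 64 x 128 pixels with the same conventions as the full
#' detector; property tests that are exhaustive over pixels use this.
#'
#' @inheritParams detector_geometry
#' @return an `sfx_geometry`.
#' @export
mini_geometry <- function(gains = rep(1.0, 8L), beam_center_mm = c(0, 0)) {
  detector_geometry(n_modules = 8L, fast_extent = 64L, slow_extent = 128L,
                    gains = gains, beam_center_mm = beam_center_mm)
}

#' @export
print.sfx_geometry <- function(x, ...) {
  p <- x$panels[[1]]
  cat(sprintf("<sfx_geometry> %d modules of %d x %d px (fast x slow)\n",
              x$n_modules, p$fast_extent, p$slow_extent))
  cat(sprintf("  stacked array: %d x %d (rows x cols)\n",
              stacked_shape(x)[1], stacked_shape(x)[2]))
  cat(sprintf("  pixel %.4g mm, camera length %.4g mm\n",
              p$pixel_size, x$camera_length_mm))
  invisible(x)
}

is_geometry <- function(x) inherits(x, "sfx_geometry")

assert_geometry <- function(geometry) {
  if (!is_geometry(geometry)) stop("not an sfx_geometry object")
  if (length(geometry$panels) != geometry$n_modules)
    stop("invalid geometry: panel count does not match n_modules")
  invisible(geometry)
}

#' Shape of the stacked raw array
#'
#' The raw in-memory layout stacks the module panels along the slow axis:
#' rows = `n_modules * slow_extent` (8192 for the full detector), columns =
#' `fast_extent` (512).
#'
#' @param geometry an [detector_geometry()] object.
#' @return integer vector `c(rows, cols)`.
#' @export
stacked_shape <- function(geometry) {
  assert_geometry(geometry)
  if (geometry$n_modules != 8L)
    stop("invalid geometry: expected 8 panels, got ", geometry$n_modules)
  c(sum(vapply(geometry$panels, `[[`, integer(1), "slow_extent")),
    geometry$panels[[1]]$fast_extent)
}

#' Map a module-local pixel to its stacked-array index and back
#'
#' `module_pixel_to_stacked()` maps 0-based `(module, fast, slow)` to
#' 0-based `(row, col)` in the stacked array; `stacked_to_module_pixel()`
#' is its inverse.  The mapping is a bijection over all pixels.
#'
#' @param geometry an `sfx_geometry`.
#' @param module 0-based module index.
#' @param fast,slow 0-based pixel indices within the panel.
#' @return `module_pixel_to_stacked`: c(row, col); `stacked_to_module_pixel`:
#'   c(module, fast, slow).  All 0-based.
#' @export
module_pixel_to_stacked <- function(geometry, module, fast, slow) {
  check_pixel(geometry, module, fast, slow)
  p <- geometry$panels[[module + 1L]]
  c(row = module * p$slow_extent + slow, col = fast)
}

#' @rdname module_pixel_to_stacked
#' @param row,col 0-based stacked-array indices.
#' @export
stacked_to_module_pixel <- function(geometry, row, col) {
  assert_geometry(geometry)
  se <- geometry$panels[[1]]$slow_extent
  fe <- geometry$panels[[1]]$fast_extent
  if (row < 0 || row >= geometry$n_modules * se || col < 0 || col >= fe)
    stop("stacked index out of range")
  m <- row %/% se
  c(module = m, fast = col, slow = row %% se)
}

check_pixel <- function(geometry, module, fast, slow) {
  assert_geometry(geometry)
  if (module < 0 || module >= geometry$n_modules)
    stop("module index out of range: ", module)
  p <- geometry$panels[[module + 1L]]
  if (any(fast < 0 | fast >= p$fast_extent) ||
      any(slow < 0 | slow >= p$slow_extent))
    stop("pixel index out of range")
  invisible(p)
}

#' Lab-frame position of a pixel
#'
#' Position of the center of pixel `(fast, slow)` of module `module`:
#' `origin + fast * fast_axis * pixel_size + slow * slow_axis * pixel_size`.
#' Vectorized over `fast` and `slow`.
#'
#' @inheritParams module_pixel_to_stacked
#' @return numeric `c(x_mm, y_mm)` (or a 2-column matrix when vectorized).
#' @export
pixel_to_lab <- function(geometry, module, fast, slow) {
  p <- check_pixel(geometry, module, fast, slow)
  x <- p$origin_lab[1] + fast * p$fast_axis[1] * p$pixel_size +
    slow * p$slow_axis[1] * p$pixel_size
  y <- p$origin_lab[2] + fast * p$fast_axis[2] * p$pixel_size +
    slow * p$slow_axis[2] * p$pixel_size
  if (length(x) == 1L) c(x = x, y = y) else cbind(x = x, y = y)
}

#' Stack / unstack module panels
#'
#' @param panels list of `slow x fast` matrices, one per module.
#' @return `stack_panels`: one `(n_modules*slow) x fast` matrix.
#' @export
stack_panels <- function(panels) do.call(rbind, panels)

#' @rdname stack_panels
#' @param stacked a stacked matrix.
#' @param geometry the geometry describing the layout.
#' @export
unstack_panels <- function(stacked, geometry) {
  assert_geometry(geometry)
  se <- geometry$panels[[1]]$slow_extent
  lapply(seq_len(geometry$n_modules) - 1L, function(m)
    stacked[(m * se + 1L):((m + 1L) * se), , drop = FALSE])
}

#' Write / read a CrystFEL-style geometry file
#'
#' Emits the key/value `.geom` dialect understood by CrystFEL-family tools:
#' one block per panel with `pN/min_fs`, `pN/max_fs`, `pN/min_ss`,
#' `pN/max_ss`, `pN/corner_x`, `pN/corner_y` (in pixel units relative to
#' the beam axis), `pN/fs`, `pN/ss` axis strings and `pN/res`, plus global
#' `clen` (in m) and a `photon_energy` placeholder.  `read_geom_file()`
#' parses a file written by `write_geom_file()` back into an equivalent
#' `sfx_geometry`; the round trip is the identity on all geometry fields.
#'
#' @param geometry an `sfx_geometry`.
#' @param path file path to write to / read from.
#' @return `write_geom_file` returns `path` invisibly; `read_geom_file`
#'   returns an `sfx_geometry`.
#' @export
write_geom_file <- function(geometry, path) {
  assert_geometry(geometry)
  px <- geometry$panels[[1]]$pixel_size
  lines <- c(
    "; detector geometry (CrystFEL-style dialect)",
    sprintf("clen = %.9g", geometry$camera_length_mm / 1000),
    "photon_energy = /metadata/photon_energy_ev",
    sprintf("res = %.9g", 1000 / px),  # pixels per metre
    sprintf("; beam_center_mm = %.9g %.9g",
            geometry$beam_center_mm[1], geometry$beam_center_mm[2]),
    "")
  for (p in geometry$panels) {
    m <- p$index
    pre <- sprintf("p%d", m)
    corner <- (p$origin_lab - geometry$beam_center_mm) / p$pixel_size
    lines <- c(lines,
      sprintf("%s/min_fs = 0", pre),
      sprintf("%s/max_fs = %d", pre, p$fast_extent - 1L),
      sprintf("%s/min_ss = %d", pre, m * p$slow_extent),
      sprintf("%s/max_ss = %d", pre, (m + 1L) * p$slow_extent - 1L),
      sprintf("%s/corner_x = %.9g", pre, corner[1]),
      sprintf("%s/corner_y = %.9g", pre, corner[2]),
      sprintf("%s/fs = %+gx %+gy", pre, p$fast_axis[1], p$fast_axis[2]),
      sprintf("%s/ss = %+gx %+gy", pre, p$slow_axis[1], p$slow_axis[2]),
      sprintf("%s/coffset = 0", pre),
      sprintf("%s/adu_per_photon_gain = %.9g", pre, geometry$gains[m + 1L]),
      "")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_geom_file
#' @export
read_geom_file <- function(path) {
  raw <- readLines(path)
  bc <- c(0, 0)
  bc_line <- grep("^; beam_center_mm = ", raw, value = TRUE)
  if (length(bc_line) == 1L)
    bc <- as.numeric(strsplit(sub("^; beam_center_mm = ", "", bc_line),
                              " ")[[1]])
  raw <- sub(";.*$", "", raw)
  raw <- raw[grepl("=", raw)]
  kv <- do.call(rbind, strsplit(raw, "\\s*=\\s*"))
  keys <- trimws(kv[, 1]); vals <- trimws(kv[, 2])
  val <- function(k) vals[match(k, keys)]
  clen_mm <- as.numeric(val("clen")) * 1000
  px <- 1000 / as.numeric(val("res"))
  pn <- grep("^p[0-9]+/min_fs$", keys, value = TRUE)
  n <- length(pn)
  parse_axis <- function(s) {
    m <- regmatches(s, gregexpr("[+-]?[0-9.]+(?=[xy])", s, perl = TRUE))[[1]]
    as.numeric(m)
  }
  panels <- lapply(seq_len(n) - 1L, function(m) {
    pre <- sprintf("p%d", m)
    fe <- as.integer(val(paste0(pre, "/max_fs"))) -
      as.integer(val(paste0(pre, "/min_fs"))) + 1L
    se <- as.integer(val(paste0(pre, "/max_ss"))) -
      as.integer(val(paste0(pre, "/min_ss"))) + 1L
    corner <- c(as.numeric(val(paste0(pre, "/corner_x"))),
                as.numeric(val(paste0(pre, "/corner_y"))))
    list(index = m, fast_extent = fe, slow_extent = se,
         origin_lab = corner * px + bc,
         fast_axis = parse_axis(val(paste0(pre, "/fs"))),
         slow_axis = parse_axis(val(paste0(pre, "/ss"))),
         pixel_size = px)
  })
  gains <- vapply(seq_len(n) - 1L, function(m)
    as.numeric(val(sprintf("p%d/adu_per_photon_gain", m))), numeric(1))
  structure(list(panels = panels, n_modules = n,
                 camera_length_mm = clen_mm, beam_center_mm = bc,
                 gains = gains),
            class = "sfx_geometry")
}

#' Serialize a geometry to / from the pipeline's own YAML config
#'
#' @param geometry an `sfx_geometry`.
#' @param path YAML file path.
#' @return `read_geometry_yaml` returns an `sfx_geometry`.
#' @export
write_geometry_yaml <- function(geometry, path) {
  assert_geometry(geometry)
  p <- geometry$panels[[1]]
  yaml::write_yaml(list(
    n_modules = geometry$n_modules,
    fast_extent = p$fast_extent, slow_extent = p$slow_extent,
    pixel_size_mm = p$pixel_size,
    camera_length_mm = geometry$camera_length_mm,
    beam_center_mm = as.list(geometry$beam_center_mm),
    gains = as.list(geometry$gains)), path)
  invisible(path)
}

#' @rdname write_geometry_yaml
#' @export
read_geometry_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  detector_geometry(n_modules = y$n_modules, fast_extent = y$fast_extent,
                    slow_extent = y$slow_extent,
                    pixel_size_mm = y$pixel_size_mm,
                    camera_length_mm = y$camera_length_mm,
                    beam_center_mm = unlist(y$beam_center_mm),
                    gains = unlist(y$gains))
}
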