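#' Event-store configuration
#'
#' Multi-event HDF5 layout: one group `tag-N` per image (N = the pulse tag
#' number), holding the stacked calibrated image and its metadata.  Images
#' are compressed with the standard HDF5 deflate filter -- decompression
#' is transparent to any HDF5 reader and no side-car tools are needed.
#' Group names are tag-based because a tag is a unique constant of the
#' pulse, while an index into a 3-D stack would change on reprocessing.
#'
#' @param level deflate level 0-9 (default 5; 0 stores uncompressed).
#' @param chunk chunk shape for the image dataset; default one module
#'   panel per chunk.
#' @return an object of class `sfx_store_config`.
#' @export
store_config <- function(level = 5L, chunk = NULL) {
  level <- as.integer(level)
  stopifnot(level >= 0L, level <= 9L)
  structure(list(level = level, chunk = chunk), class = "sfx_store_config")
}

tag_group <- function(tag) sprintf("tag-%.0f", tag)

#' Build an event record from a calibrated frame
#'
#' @param frame an `sfx_cal_frame`.
#' @param spots an `sfx_spotlist` for the same frame (optional).
#' @return an `sfx_event`: stacked int16 image plus metadata and the spot
#'   table.
#' @export
event_record <- function(frame, spots = NULL) {
  stopifnot(inherits(frame, "sfx_cal_frame"))
  if (!is.null(spots) && !isTRUE(all.equal(spots$tag, frame$tag)))
    stop("spot list tag does not match frame tag")
  structure(list(tag = frame$tag,
                 image = stack_panels(frame$panels),
                 photon_energy_ev = frame$photon_energy_ev,
                 spectrum_mean_ev = frame$spectrum_mean_ev %||% NA_real_,
                 photodiode = frame$photodiode %||% NA_real_,
                 n_spots = if (is.null(spots)) NA_integer_ else
                   nrow(spots$spots),
                 spots = if (is.null(spots)) NULL else spots$spots),
            class = "sfx_event")
}

#' Open, append to, and close a multi-event store
#'
#' Streaming interface used by the pipeline so that a full run never needs
#' to be held in memory.  `open_event_store()` creates the file and its
#' `/metadata` group; `append_event()` writes one `tag-N` group (duplicate
#' tags are rejected before anything is written); `close_event_store()`
#' releases HDF5 handles.
#'
#' @param path HDF5 file path (overwritten).
#' @param config an [store_config()].
#' @param metadata named list written under `/metadata` (e.g. `run_id`,
#'   geometry file reference, parameter snapshot strings).
#' @return `open_event_store` returns a store handle.
#' @export
open_event_store <- function(path, config = store_config(),
                             metadata = list()) {
  stopifnot(inherits(config, "sfx_store_config"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "metadata")
  for (nm in names(metadata))
    rhdf5::h5write(metadata[[nm]], path, paste0("metadata/", nm))
  rhdf5::h5closeAll()
  structure(list(path = path, config = config,
                 env = local({e <- new.env(); e$tags <- numeric(0); e})),
            class = "sfx_event_store")
}

#' @rdname open_event_store
#' @param store a store handle from `open_event_store()`.
#' @param event an [event_record()].
#' @export
append_event <- function(store, event) {
  stopifnot(inherits(store, "sfx_event_store"), inherits(event, "sfx_event"))
  if (event$tag %in% store$env$tags)
    stop("duplicate tag: ", tag_group(event$tag))
  path <- store$path
  grp <- tag_group(event$tag)
  level <- store$config$level
  img <- event$image
  chunk <- store$config$chunk %||% c(nrow(img) %/% 8L, ncol(img))
  chunk <- pmin(chunk, dim(img))
  rhdf5::h5createGroup(path, grp)
  rhdf5::h5createDataset(path, paste0(grp, "/data"), dims = dim(img),
                         H5type = "H5T_STD_I16LE", chunk = chunk,
                         level = level,
                         filter = if (level == 0L) "NONE" else "GZIP")
  rhdf5::h5write(img, path, paste0(grp, "/data"))
  rhdf5::h5write(event$tag, path, paste0(grp, "/tag"))
  rhdf5::h5write(event$photon_energy_ev, path,
                 paste0(grp, "/photon_energy_ev"))
  rhdf5::h5write(event$spectrum_mean_ev, path,
                 paste0(grp, "/spectrum_mean_ev"))
  rhdf5::h5write(event$photodiode, path, paste0(grp, "/photodiode"))
  rhdf5::h5write(as.integer(event$n_spots), path, paste0(grp, "/n_spots"))
  if (!is.null(event$spots) && nrow(event$spots) > 0) {
    s <- event$spots
    # column order fixed as (fs, ss, panel, intensity, snr); HDF5 drops
    # the dimnames
    rhdf5::h5write(cbind(s$fast, s$slow, s$module, s$intensity, s$snr),
                   path, paste0(grp, "/peaks"))
  }
  rhdf5::h5closeAll()
  store$env$tags <- c(store$env$tags, event$tag)
  invisible(store)
}

#' @rdname open_event_store
#' @export
close_event_store <- function(store) {
  rhdf5::h5closeAll()
  invisible(store$path)
}

#' Write a set of events to a multi-event HDF5 file
#'
#' Convenience wrapper around the streaming store.  Duplicate tags are
#' rejected before any write; on a write failure the partial file is
#' removed.
#'
#' @param path output HDF5 file (overwritten).
#' @param events list of [event_record()]s.
#' @param config an [store_config()].
#' @param metadata named list for the file-level `/metadata` group.
#' @return `path`, invisibly.
#' @export
write_events <- function(path, events, config = store_config(),
                         metadata = list()) {
  tags <- vapply(events, `[[`, numeric(1), "tag")
  if (anyDuplicated(tags)) stop("duplicate tags in event set")
  store <- open_event_store(path, config, metadata)
  tryCatch({
    for (ev in events) append_event(store, ev)
  }, error = function(e) {
    rhdf5::h5closeAll()
    unlink(path)
    stop("event store write failed; partial file removed: ",
         conditionMessage(e))
  })
  close_event_store(store)
  invisible(path)
}

#' Read one event back from a store
#'
#' @param path HDF5 file.
#' @param tag tag number.
#' @return an `sfx_event`.
#' @export
read_event <- function(path, tag) {
  grp <- tag_group(tag)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  root <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!grp %in% root) stop("tag not found in store: ", grp)
  members <- rhdf5::h5ls(path, recursive = TRUE)
  in_grp <- members$name[members$group == paste0("/", grp)]
  rd <- function(nm) rhdf5::h5read(path, paste0(grp, "/", nm))
  img <- rd("data")
  storage.mode(img) <- "integer"
  spots <- NULL
  if ("peaks" %in% in_grp) {
    pk <- rd("peaks")
    spots <- data.frame(module = as.integer(pk[, 3]),
                        fast = pk[, 1], slow = pk[, 2],
                        intensity = pk[, 4], snr = pk[, 5])
  }
  structure(list(tag = as.numeric(rd("tag")),
                 image = img,
                 photon_energy_ev = as.numeric(rd("photon_energy_ev")),
                 spectrum_mean_ev = as.numeric(rd("spectrum_mean_ev")),
                 photodiode = as.numeric(rd("photodiode")),
                 n_spots = as.integer(rd("n_spots")),
                 spots = spots),
            class = "sfx_event")
}

#' List the tags stored in a multi-event file
#'
#' Ascending tag numbers parsed from `tag-N` group names; non-conforming
#' groups (other than `/metadata`) are ignored with a warning.
#'
#' @param path HDF5 file.
#' @return sorted numeric vector of tags.
#' @export
list_tags <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  groups <- ls$name[ls$otype == "H5I_GROUP"]
  conform <- grepl("^tag-[0-9]+$", groups)
  other <- setdiff(groups[!conform], "metadata")
  if (length(other) > 0)
    warning("ignoring non-conforming groups: ",
            paste(other, collapse = ", "))
  sort(as.numeric(sub("^tag-", "", groups[conform])))
}

#' Export the raw frames of a synthetic run as HDF5
#'
#' One `tag-N` group per frame holding the stacked unsigned 16-bit raw
#' panels and shot metadata; used by the CLI `simulate` subcommand.
#'
#' @param run an [synthetic_run()].
#' @param path output file.
#' @param level deflate level.
#' @return `path`, invisibly.
#' @export
write_raw_run <- function(run, path, level = 5L) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "metadata")
  rhdf5::h5write(run$manifest$run_id, path, "metadata/run_id")
  rhdf5::h5write(run$manifest$n_dark, path, "metadata/n_dark")
  rhdf5::h5write(run$manifest$photon_energy_ev, path,
                 "metadata/photon_energy_ev")
  for (i in seq_len(n_frames(run))) {
    f <- get_frame(run, i)
    grp <- tag_group(f$tag)
    img <- stack_panels(f$panels)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5createDataset(path, paste0(grp, "/data"), dims = dim(img),
                           H5type = "H5T_STD_U16LE",
                           chunk = c(nrow(img) %/% length(f$panels),
                                     ncol(img)),
                           level = level,
                           filter = if (level == 0L) "NONE" else "GZIP")
    rhdf5::h5write(img, path, paste0(grp, "/data"))
    rhdf5::h5write(as.integer(f$shutter_open), path,
                   paste0(grp, "/shutter_open"))
    rhdf5::h5write(f$photodiode, path, paste0(grp, "/photodiode"))
    rhdf5::h5write(f$spectrum_mean_ev, path, paste0(grp, "/spectrum_mean_ev"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}
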