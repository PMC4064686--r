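#' Write a synthetic movie to disk (multi-page TIFF + JSON metadata)
#'
#' Pages are ordered t-major, then z, then channel; the sidecar JSON carries
#' channel names, voxel sizes and the frame interval, and the truth tables go
#' to CSV next to the TIFF.
#'
#' @param movie a `synthetic_movie`
#' @param path output TIFF path; `<path>.json` and `<path>_truth.csv` are
#'   written alongside
#' @param scale intensity scale mapped to TIFF range 1.0 (32-bit float pages)
#' @return invisibly, the paths written
#' @export
write_movie_tiff <- function(movie, path, scale = 256) {
  d <- dim(movie$intensities)
  pages <- list()
  for (tix in seq_len(d[1])) for (k in seq_len(d[2])) for (ch in seq_len(d[3]))
    pages[[length(pages) + 1]] <- movie$intensities[tix, k, ch, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = movie$channels,
               n_frames = d[1], n_slices = d[2],
               px_size_um = movie$px_size_um, z_step_um = movie$z_step_um,
               frame_interval_s = movie$frame_interval_s,
               intensity_scale = scale,
               page_order = "t, z, channel")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  paths <- c(tiff = path, json = paste0(path, ".json"))
  if (!is.null(movie$truth)) {
    tp <- sub("\\.tiff?$", "", path)
    tp <- paste0(tp, "_truth.csv")
    utils::write.csv(movie$truth$truth, tp, row.names = FALSE)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path with its `<path>.json` sidecar
#' @return list with `intensities` (t,z,c,y,x), `channels`, `px_size_um`,
#'   `z_step_um`, `frame_interval_s` (a `synthetic_movie`-compatible object)
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- meta$n_frames; nz <- meta$n_slices; nc <- length(meta$channels)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nt, nz, nc, ny, nx),
               dimnames = list(NULL, NULL, meta$channels, NULL, NULL))
  i <- 1L
  for (tix in seq_len(nt)) for (k in seq_len(nz)) for (ch in seq_len(nc)) {
    arr[tix, k, ch, , ] <- pages[[i]] * meta$intensity_scale
    i <- i + 1L
  }
  structure(list(intensities = arr, channels = meta$channels,
                 px_size_um = meta$px_size_um, z_step_um = meta$z_step_um,
                 frame_interval_s = meta$frame_interval_s, truth = NULL),
            class = "synthetic_movie")
}

#' Write a surface map as 32-bit TIFF (heights in um mapped by `scale`)
#' @param surface a `surface_map`
#' @param path output path
#' @param scale um mapped to 1.0
#' @export
write_surface_tiff <- function(surface, path, scale = 64) {
  tiff::writeTIFF(surface$height / scale, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write tracked cell instances to CSV
#' @param tracks a `cell_tracks` (or the traces table of an analysis)
#' @param path output CSV path
#' @export
write_tracks_csv <- function(tracks, path) {
  tab <- if (inherits(tracks, "cell_tracks")) tracks$instances else tracks
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' JSON summary of a placode analysis
#'
#' @param analysis a `placode_analysis`
#' @param path output JSON path
#' @param extra named list merged into the summary
#' @export
write_analysis_summary <- function(analysis, path, extra = list()) {
  s <- c(list(
    schema_version = "1.0",
    pct_myosin_fluct = analysis$fractions$pct_myosin_fluct,
    pct_radius_given_myosin = analysis$fractions$pct_radius_given_myosin,
    counts = analysis$fractions$counts,
    mean_cycle_length_s = analysis$mean_cycle_length_s,
    lead_cycles = analysis$phase_avg$lead_cycles,
    thresholds = analysis$thresholds), extra)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
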