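#' Default synthetic placode movie
#'
#' One call producing the standard study scene: 150 cells on an 80 x 80 um
#' field, 15 min at 20 s frames, 150 s mean cycle with the inverse radius
#' trailing myosin by one-eighth of a cycle, rendered on the default dome
#' with default optics.
#'
#' @param seed integer seed driving geometry, dynamics and rendering
#' @param n_cells,duration_s scene size overrides
#' @param params an `oscillation_params`
#' @param optics a `render_optics`
#' @return a `synthetic_movie`
#' @export
default_movie <- function(seed = 1L, n_cells = 150, duration_s = 900,
                          params = oscillation_params(),
                          optics = render_optics()) {
  geom <- generate_epithelium(n_cells, seed = seed)
  dyn <- simulate_dynamics(geom, params, duration = duration_s,
                           seed = seed + 1L)
  render_movie(dyn, optics, seed = seed + 2L)
}

#' Run the full fluctuation-analysis pipeline on a movie
#'
#' Chains surface projection, segmentation, tracking, QC, intensity
#' quantification, detrending, cycle detection, activity classification,
#' pooled fluctuation fractions, phase averaging and radial profiles — the
#' complete analysis a placode movie undergoes.
#'
#' @param movie a `synthetic_movie` (or compatible object)
#' @param pit_center pit position, um; defaults to the movie's ground truth
#'   when available
#' @param placode_poly polygon (um) delimiting placodal cells; defaults to the
#'   generating ellipse for synthetic movies
#' @param thresholds list(myosin =, radius =) activity thresholds
#' @param detrend_window_s boxcar window, s
#' @param band_width_um junctional band width, um
#' @param qc list of [qc_filter()] arguments (NULL = defaults)
#' @return list of class `placode_analysis` with elements `frames`, `tracks`,
#'   `traces` (per-instance table with detrended signals, cycles, phases,
#'   activities), `cycles_myosin`, `cycles_radius`, `fractions`,
#'   `phase_avg`, `radial_activity`, `radial_rate`, `mean_cycle_length_s`
#' @export
run_placode_pipeline <- function(movie, pit_center = NULL,
                                 placode_poly = NULL,
                                 thresholds = list(myosin = 0.5, radius = 0.005),
                                 detrend_window_s = 360,
                                 band_width_um = 0.6, qc = NULL) {
  geom <- if (!is.null(movie$truth)) movie$truth$geom else NULL
  if (is.null(pit_center) && !is.null(geom)) pit_center <- geom$pit_center
  if (is.null(pit_center)) stop("pit_center is required")
  if (is.null(placode_poly)) {
    if (is.null(geom)) stop("placode_poly is required for non-synthetic input")
    placode_poly <- ellipse_polygon(geom$domain / 2, 0.48 * geom$domain)
  }

  frames <- project_movie(movie)
  tracks <- track_cells(frames)
  tracks <- do.call(qc_filter, c(list(tracks), qc))
  tracks <- flag_placode(tracks, placode_poly)

  # baseline: pixels outside a slightly grown placode outline, off-skeleton
  px <- frames$px_size_um
  ny <- nrow(frames$myosin[[1]]); nx <- ncol(frames$myosin[[1]])
  xs <- (seq_len(nx) - 0.5) * px; ys <- (seq_len(ny) - 0.5) * px
  gx <- rep(xs, each = ny); gy <- rep(ys, times = nx)
  ctr <- colMeans(placode_poly)
  grown <- sweep(sweep(placode_poly, 2, ctr) * 1.08, 2, ctr, "+")
  baseline_mask <- matrix(!points_in_poly(gx, gy, grown), ny, nx)
  if (!any(baseline_mask)) baseline_mask <- matrix(TRUE, ny, nx)

  traces <- quantify_traces(frames, tracks, baseline_mask, band_width_um)
  coords <- assign_placode_coordinates(traces$centroid_x_um,
                                       traces$centroid_y_um, pit_center)
  traces <- cbind(traces, coords)

  # per-track detrending, cycle detection, classification
  traces$detrended_myosin <- NA_real_
  traces$detrended_inv_radius <- NA_real_
  traces$cycle_id_myosin <- NA_integer_; traces$phase_myosin <- NA_real_
  traces$activity_myosin <- NA_real_
  traces$fluct_myosin <- NA; traces$fluct_radius <- NA
  cyc_m_all <- list(); cyc_r_all <- list()
  min_len <- max(5, ceiling(detrend_window_s / max(frames$frame_interval_s, 1)))
  for (id in unique(traces$cell_id)) {
    sel <- which(traces$cell_id == id & traces$valid_flag &
                   traces$placode_flag %in% TRUE)
    if (length(sel) < min_len) next
    tt <- traces$t_s[sel]
    myo <- traces$medial_gs[sel]
    if (anyNA(myo)) next
    invr <- 1 / traces$radius_um[sel]
    dm <- detrend(myo, tt, detrend_window_s)
    dr <- detrend(invr, tt, detrend_window_s)
    # mask gross outliers (transient segmentation faults that slip past QC):
    # instances beyond 5 robust sds of their own trace corrupt pooled bins
    mask_out <- function(x) {
      s <- stats::mad(x)
      if (s > 0) x[abs(x) > 5 * s] <- NA
      x
    }
    traces$detrended_myosin[sel] <- mask_out(dm$detrended)
    traces$detrended_inv_radius[sel] <- mask_out(dr$detrended)
    cm <- detect_cycles(dm$detrended, tt, "myosin")
    # radius cycles are defined peak-to-peak on the radius itself
    drr <- detrend(traces$radius_um[sel], tt, detrend_window_s)
    cr <- detect_cycles(drr$detrended, tt, "radius")
    am <- classify_activity(tt, cm, thresholds$myosin)
    ar <- classify_activity(tt, cr, thresholds$radius)
    traces$cycle_id_myosin[sel] <- am$cycle_id
    traces$phase_myosin[sel] <- am$phase
    traces$activity_myosin[sel] <- am$activity
    traces$fluct_myosin[sel] <- am$fluctuating
    traces$fluct_radius[sel] <- ar$fluctuating
    if (nrow(cm)) { cm$cell_id <- id; cyc_m_all[[length(cyc_m_all) + 1]] <- cm }
    if (nrow(cr)) { cr$cell_id <- id; cyc_r_all[[length(cyc_r_all) + 1]] <- cr }
  }
  cycles_myosin <- if (length(cyc_m_all)) do.call(rbind, cyc_m_all) else NULL
  cycles_radius <- if (length(cyc_r_all)) do.call(rbind, cyc_r_all) else NULL

  analyzed <- !is.na(traces$fluct_myosin)
  fractions <- fluctuation_fractions(traces$fluct_myosin[analyzed],
                                     traces$fluct_radius[analyzed])
  phase_avg <- phase_average(traces$phase_myosin, traces$detrended_myosin,
                             traces$detrended_inv_radius)
  keep <- analyzed & !is.na(traces$activity_myosin)
  act_filled <- ifelse(is.na(traces$activity_myosin), 0,
                       traces$activity_myosin)
  radial_activity <- radial_profile(act_filled[analyzed],
                                    traces$r_um[analyzed])
  # pooled per-cell relative area-change rate, per radial bin
  rates <- rep(NA_real_, nrow(traces))
  for (id in unique(traces$cell_id)) {
    sel <- which(traces$cell_id == id & traces$valid_flag)
    if (length(sel) >= 3)
      rates[sel] <- area_change_rate(traces$t_s[sel], traces$area_um2[sel],
        frame_interval_s = frames$frame_interval_s)$dlnA_dt_min
  }
  ok <- !is.na(rates) & traces$placode_flag %in% TRUE
  radial_rate <- if (any(ok)) radial_profile(rates[ok], traces$r_um[ok]) else NULL

  structure(list(
    frames = frames, tracks = tracks, traces = traces,
    cycles_myosin = cycles_myosin, cycles_radius = cycles_radius,
    fractions = fractions, phase_avg = phase_avg,
    radial_activity = radial_activity, radial_rate = radial_rate,
    mean_cycle_length_s = if (!is.null(cycles_myosin))
      mean(cycles_myosin$length_s) else NA_real_,
    thresholds = thresholds), class = "placode_analysis")
}

#' @export
print.placode_analysis <- function(x, ...) {
  cat("placode_analysis\n")
  cat(sprintf("  instances analyzed: %d (of %d tracked)\n",
              x$fractions$counts$total, nrow(x$traces)))
  cat(sprintf("  myosin-fluctuating: %.0f%%; radius|myosin: %.0f%%\n",
              x$fractions$pct_myosin_fluct, x$fractions$pct_radius_given_myosin))
  cat(sprintf("  mean myosin cycle length: %.0f s; myosin lead: %.3f cycles\n",
              x$mean_cycle_length_s, x$phase_avg$lead_cycles))
  invisible(x)
}
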