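#' Per-cell apical geometry from a polygon
#'
#' Area by the shoelace formula, centroid by the polygon-centroid formula, and
#' a scalar cell radius. The radius convention is switchable: the default
#' equivalent-circle radius sqrt(area/pi), or the mean centroid-to-vertex
#' distance.
#'
#' @param polygon n x 2 vertex matrix, um
#' @param radius_mode "equivalent_circle" (default) or "centroid_vertex_mean"
#' @return list with `area_um2`, `radius_um`, `centroid` (x, y um)
#' @export
measure_geometry <- function(polygon,
                             radius_mode = c("equivalent_circle",
                                             "centroid_vertex_mean")) {
  radius_mode <- match.arg(radius_mode)
  if (!poly_is_simple(polygon)) stop("polygon is self-intersecting")
  a <- poly_area(polygon)
  ctr <- poly_centroid(polygon)
  r <- switch(radius_mode,
    equivalent_circle = sqrt(a / pi),
    centroid_vertex_mean = mean(sqrt((polygon[, 1] - ctr[1])^2 +
                                     (polygon[, 2] - ctr[2])^2)))
  list(area_um2 = a, radius_um = r, centroid = ctr)
}

#' Neighbor dispersion of apical areas
#'
#' For every cell, the mean absolute difference in apical area between the
#' cell and its edge-sharing neighbors. High dispersion marks spatially
#' scattered (unclustered) constriction; coordinated constriction gives low
#' dispersion. Cells without neighbors get NA and are excluded from summaries.
#'
#' @param labels integer label image; neighbors are derived from shared
#'   boundaries (ignored when `adjacency` is given)
#' @param areas numeric vector of areas, um^2, indexed by cell id
#' @param adjacency optional 2-column matrix of neighbor cell-id pairs
#' @return data.frame (cell_id, D_um2)
#' @export
neighbor_dispersion <- function(labels = NULL, areas, adjacency = NULL) {
  adj <- if (is.null(adjacency)) derive_adjacency(labels) else adjacency
  ids <- seq_along(areas)
  if (nrow(adj) == 0)
    return(data.frame(cell_id = ids, D_um2 = NA_real_))
  both <- rbind(adj, adj[, 2:1])
  dif <- abs(areas[both[, 1]] - areas[both[, 2]])
  D <- rep(NA_real_, length(areas))
  agg <- tapply(dif, both[, 1], mean)
  D[as.integer(names(agg))] <- agg
  data.frame(cell_id = ids, D_um2 = D)
}

#' Pit-centered placode coordinates
#'
#' Imposes the standard placode frame: origin at the invagination-pit center,
#' anterior distance increasing to the left (-x) and ventral distance
#' increasing downward (-y), per the usual display convention. The radial
#' coordinate r is the Euclidean centroid distance to the pit.
#'
#' @param x_um,y_um instance centroid coordinates, um
#' @param pit_center length-2 (x, y), um; required
#' @return data.frame (r_um, angle_rad, anterior_um, ventral_um)
#' @export
assign_placode_coordinates <- function(x_um, y_um, pit_center) {
  if (missing(pit_center) || is.null(pit_center)) stop("pit_center is required")
  dx <- x_um - pit_center[1]; dy <- y_um - pit_center[2]
  data.frame(r_um = sqrt(dx^2 + dy^2), angle_rad = atan2(dy, dx),
             anterior_um = -dx, ventral_um = -dy)
}

#' Radial profile of a per-instance quantity
#'
#' Pools all cell instances into half-open radial bins [lo, hi) of width
#' `bin_width_um` and reports the per-bin mean with a normal-approximation
#' 95% confidence interval (mean +/- 1.96 SEM). Empty bins are reported with
#' n = 0.
#'
#' @param values per-instance scalar
#' @param r_um per-instance radial coordinate, um
#' @param bin_width_um bin width, um (default 5, matching the granularity of
#'   radial-band reporting in placode studies)
#' @return data.frame (bin_lo, bin_hi, mean, ci_lo, ci_hi, n)
#' @export
radial_profile <- function(values, r_um, bin_width_um = 5) {
  if (bin_width_um <= 0) stop("bin_width_um must be positive")
  stopifnot(length(values) == length(r_um), length(values) >= 1)
  keep <- !is.na(values) & !is.na(r_um)
  values <- values[keep]; r_um <- r_um[keep]
  nb <- max(1, ceiling(max(r_um) / bin_width_um + 1e-12))
  bin <- pmin(floor(r_um / bin_width_um), nb - 1) + 1
  out <- data.frame(bin_lo = (seq_len(nb) - 1) * bin_width_um,
                    bin_hi = seq_len(nb) * bin_width_um,
                    mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    n = 0L)
  for (b in seq_len(nb)) {
    v <- values[bin == b]
    out$n[b] <- length(v)
    if (length(v)) {
      m <- mean(v)
      sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
      out$mean[b] <- m; out$ci_lo[b] <- m - 1.96 * sem
      out$ci_hi[b] <- m + 1.96 * sem
    }
  }
  out
}

#' Windowed area-change rates along a track
#'
#' Least-squares slope of A(t) and of ln A(t) over a centered window
#' (default 60 s) around each instance. Negative rates are constriction.
#' Instances whose window holds fewer than 3 samples get NA.
#'
#' @param t_s instance times, s (strictly increasing)
#' @param area_um2 instance areas, um^2
#' @param window_s window width, s; must span at least 2 frame intervals
#' @param frame_interval_s nominal sampling interval, s; defaults to the
#'   smallest observed time step (tracks with QC gaps can step wider)
#' @return data.frame (dA_dt_um2_min, dlnA_dt_min)
#' @export
area_change_rate <- function(t_s, area_um2, window_s = 60,
                             frame_interval_s = NULL) {
  stopifnot(length(t_s) == length(area_um2))
  if (is.null(frame_interval_s))
    frame_interval_s <- if (length(t_s) >= 2) min(diff(t_s)) else window_s / 2
  if (window_s < 2 * frame_interval_s)
    stop("window_s must span at least 2 frame intervals")
  n <- length(t_s)
  slope <- function(tt, vv) {
    tm <- mean(tt); vm <- mean(vv)
    sum((tt - tm) * (vv - vm)) / sum((tt - tm)^2)
  }
  dA <- rep(NA_real_, n); dlnA <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- which(abs(t_s - t_s[i]) <= window_s / 2 + 1e-9)
    if (length(w) >= 3) {
      dA[i] <- slope(t_s[w], area_um2[w]) * 60       # per min
      dlnA[i] <- slope(t_s[w], log(area_um2[w])) * 60
    }
  }
  data.frame(dA_dt_um2_min = dA, dlnA_dt_min = dlnA)
}
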