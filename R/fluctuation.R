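#' Partition a cell polygon into medial and junctional regions
#'
#' The medial region is the polygon offset inward by `band_width_um`; the
#' junctional band is the remainder. If the offset empties the polygon the
#' whole cell is junctional.
#'
#' @param polygon n x 2 vertex matrix, um
#' @param band_width_um junctional band width, um (>= 0)
#' @return list with `medial` (polygon or NULL), `junctional_area_um2`,
#'   `medial_area_um2`, `cell_area_um2`, `band_width_um`
#' @export
partition_regions <- function(polygon, band_width_um) {
  if (band_width_um < 0) stop("band_width_um must be >= 0")
  cell_a <- poly_area(polygon)
  med <- if (band_width_um == 0) polygon else
    poly_inward_offset(polygon, band_width_um)
  med_a <- if (is.null(med)) 0 else poly_area(med)
  list(medial = med, medial_area_um2 = med_a,
       junctional_area_um2 = cell_a - med_a,
       cell_area_um2 = cell_a, band_width_um = band_width_um)
}

#' Per-cell medial and junctional intensity traces from projected frames
#'
#' For every tracked instance, the mean of the projected myosin channel over
#' the cell's medial region (pixels farther than `band_width_um` from the
#' membrane skeleton) and junctional band, minus the per-frame mean over a
#' baseline mask (e.g. the epidermis outside the placode), floored at 0.
#' Instances whose medial region is empty get NA (missing), not 0.
#'
#' @param frames a `projected_frames`
#' @param tracks a `cell_tracks` segmented from the same frames
#' @param baseline_mask logical matrix (y, x): pixels defining the base level
#' @param band_width_um junctional band width, um
#' @return data.frame keyed like `tracks$instances` with added columns
#'   `medial_gs`, `junctional_gs`, `baseline_gs`
#' @export
quantify_traces <- function(frames, tracks, baseline_mask,
                            band_width_um = 0.6) {
  stopifnot(inherits(frames, "projected_frames"),
            inherits(tracks, "cell_tracks"))
  if (!any(baseline_mask)) stop("baseline_mask is empty")
  px <- frames$px_size_um
  band_px <- band_width_um / px
  ins <- tracks$instances
  ins$medial_gs <- NA_real_; ins$junctional_gs <- NA_real_
  ins$baseline_gs <- NA_real_
  for (tix in seq_along(frames$myosin)) {
    myo <- frames$myosin[[tix]]
    lab <- tracks$labels[[tix]]
    base <- mean(myo[baseline_mask])
    dist <- t(as.matrix(EBImage::distmap(t(lab > 0))))
    medial <- lab > 0 & dist > band_px
    junct <- lab > 0 & dist <= band_px
    med_m <- tapply(myo[medial], lab[medial], mean)
    jun_m <- tapply(myo[junct], lab[junct], mean)
    sel <- which(ins$frame == tix)
    id_chr <- as.character(ins$cell_id[sel])
    mm <- med_m[id_chr]; jj <- jun_m[id_chr]
    ins$medial_gs[sel] <- pmax(mm - base, 0)      # NA stays NA (empty medial)
    ins$junctional_gs[sel] <- pmax(jj - base, 0)
    ins$baseline_gs[sel] <- base
  }
  ins
}

#' Boxcar detrending of a time series
#'
#' Subtracts a centered moving mean (default window 360 s, chosen to exceed
#' the longest expected fluctuation cycle) from the raw series; the window is
#' truncated at the series ends, so trend + detrended reconstructs the raw
#' series exactly everywhere.
#'
#' @param x raw series
#' @param t_s sample times, s (strictly increasing)
#' @param window_s boxcar width, s; must span at least 2 frame intervals
#' @return data.frame (t_s, raw, trend, detrended)
#' @export
detrend <- function(x, t_s, window_s = 360) {
  stopifnot(length(x) == length(t_s), length(x) >= 3, all(diff(t_s) > 0))
  if (window_s < 2 * stats::median(diff(t_s)))
    stop("window_s must span at least 2 frame intervals")
  trend <- vapply(seq_along(x), function(i) {
    w <- abs(t_s - t_s[i]) <= window_s / 2 + 1e-9
    mean(x[w])
  }, 0)
  data.frame(t_s = t_s, raw = x, trend = trend, detrended = x - trend)
}

# Alternating extrema of a series with minimum prominence: turning points are
# pruned pairwise until every adjacent max/min pair differs by >= prominence.
find_extrema <- function(x, prominence) {
  n <- length(x)
  if (n < 3) return(data.frame(idx = integer(0), kind = character(0)))
  s <- sign(diff(x))
  if (any(s == 0)) {           # plateaus continue the preceding direction
    for (i in which(s == 0)) s[i] <- if (i == 1) 0 else s[i - 1]
    if (all(s == 0)) return(data.frame(idx = integer(0), kind = character(0)))
    first_nz <- which(s != 0)[1]
    s[seq_len(first_nz - 1)] <- s[first_nz]
  }
  turn <- which(diff(s) != 0) + 1L
  if (!length(turn)) return(data.frame(idx = integer(0), kind = character(0)))
  kind <- ifelse(s[turn - 1] > 0, "max", "min")
  idx <- turn
  # include endpoints as provisional extrema to anchor the alternation
  idx <- c(1L, idx, n)
  kind <- c(ifelse(kind[1] == "max", "min", "max"), kind,
            ifelse(kind[length(kind)] == "max", "min", "max"))
  repeat {
    if (length(idx) < 2) break
    amp <- abs(diff(x[idx]))
    k <- which.min(amp)
    if (amp[k] >= prominence) break
    drop <- if (k == 1) 1L else if (k == length(amp)) length(idx) else c(k, k + 1L)
    idx <- idx[-drop]; kind <- kind[-drop]
  }
  # drop the artificial endpoint anchors (series ends are never full extrema)
  keep <- !(idx %in% c(1L, n))
  data.frame(idx = idx[keep], kind = kind[keep], stringsAsFactors = FALSE)
}

#' Detect fluctuation cycles in a detrended trace
#'
#' Cycles run trough-to-trough for myosin and peak-to-peak for cell radius.
#' Extrema are alternating turning points with prominence at least
#' `prominence` (default 0.2 x the detrended standard deviation). Amplitude
#' is max - min of the detrended signal within the cycle; phase advances
#' linearly from 0 at the opening extremum to 1 at the closing one.
#'
#' @param detrended detrended series (from [detrend()])
#' @param t_s sample times, s
#' @param kind "myosin" (trough-to-trough) or "radius" (peak-to-peak)
#' @param prominence minimum extremum prominence, signal units; NULL uses
#'   0.3 * sd(detrended)
#' @param locate_smooth odd number of points of the moving average applied
#'   while locating extrema (1 disables); without it, per-sample shot noise
#'   splits genuine cycles at spurious turning points
#' @param amp_smooth odd number of points of the moving average applied when
#'   measuring amplitudes (1 reduces amplitude to the plain max - min of the
#'   detrended samples, which inflates amplitudes by the sample-noise
#'   envelope); kept lighter than `locate_smooth` so true pulse magnitudes
#'   survive
#' @return data.frame (cycle, start_s, end_s, length_s, amplitude,
#'   start_idx, end_idx); 0 rows when fewer than 2 qualifying extrema exist
#' @export
detect_cycles <- function(detrended, t_s, kind = c("myosin", "radius"),
                          prominence = NULL, locate_smooth = 5,
                          amp_smooth = 3) {
  kind <- match.arg(kind)
  stopifnot(length(detrended) == length(t_s), length(detrended) >= 5)
  if (is.null(prominence)) prominence <- 0.3 * stats::sd(detrended)
  boxsm <- function(x, w) {
    if (w <= 1) return(x)
    h <- (w - 1) %/% 2
    n <- length(x)
    vapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]), 0)
  }
  loc <- boxsm(detrended, locate_smooth)
  amp_series <- boxsm(detrended, amp_smooth)
  ex <- find_extrema(loc, prominence)
  anchor <- if (kind == "myosin") "min" else "max"
  an <- ex$idx[ex$kind == anchor]
  if (length(an) < 2)
    return(data.frame(cycle = integer(0), start_s = numeric(0),
                      end_s = numeric(0), length_s = numeric(0),
                      amplitude = numeric(0), start_idx = integer(0),
                      end_idx = integer(0)))
  nc <- length(an) - 1
  amp <- vapply(seq_len(nc), function(k) {
    seg <- amp_series[an[k]:an[k + 1]]
    max(seg) - min(seg)
  }, 0)
  data.frame(cycle = seq_len(nc), start_s = t_s[an[-length(an)]],
             end_s = t_s[an[-1]],
             length_s = t_s[an[-1]] - t_s[an[-length(an)]],
             amplitude = amp, start_idx = an[-length(an)], end_idx = an[-1])
}

#' Per-instance phase within detected cycles
#'
#' @param t_s instance times
#' @param cycles output of [detect_cycles()]
#' @return data.frame (cycle_id, phase); NA outside any cycle. Phase is 0 at
#'   the cycle-opening extremum and advances linearly to 1 at the closing one
#'   (cycles are half-open, so the closing instant belongs to the next cycle).
#' @export
cycle_phase <- function(t_s, cycles) {
  cyc <- rep(NA_integer_, length(t_s)); ph <- rep(NA_real_, length(t_s))
  for (k in seq_len(nrow(cycles))) {
    sel <- t_s >= cycles$start_s[k] & t_s < cycles$end_s[k]
    cyc[sel] <- cycles$cycle[k]
    ph[sel] <- (t_s[sel] - cycles$start_s[k]) / cycles$length_s[k]
  }
  data.frame(cycle_id = cyc, phase = ph)
}

#' Classify fluctuation activity of cell instances
#'
#' Every instance inside a detected cycle gets activity = that cycle's
#' amplitude x frequency (frequency = 60 / cycle length in s, per min);
#' instances at or above the threshold are fluctuating. Instances outside any
#' cycle are non-fluctuating with NA activity.
#'
#' @param t_s instance times, s
#' @param cycles output of [detect_cycles()]
#' @param threshold activity threshold: 0.5 is the standard myosin value
#'   (grayscale/min) and 0.005 the cell-radius value (um/min)
#' @return data.frame (cycle_id, phase, activity, fluctuating)
#' @export
classify_activity <- function(t_s, cycles, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  cp <- cycle_phase(t_s, cycles)
  act <- rep(NA_real_, length(t_s))
  inc <- !is.na(cp$cycle_id)
  if (any(inc)) {
    freq <- 60 / cycles$length_s
    act[inc] <- cycles$amplitude[cp$cycle_id[inc]] * freq[cp$cycle_id[inc]]
  }
  data.frame(cycle_id = cp$cycle_id, phase = cp$phase, activity = act,
             fluctuating = !is.na(act) & act >= threshold)
}

#' Pooled fluctuation fractions over classified cell instances
#'
#' The headline statistics of pulsatile-placode analyses: the percentage of
#' tracked cell instances exhibiting myosin fluctuations, and of those, the
#' percentage also exhibiting radius fluctuations. Accepts either logical
#' vectors per instance or pre-tallied counts.
#'
#' @param myosin_fluct logical per instance (or NULL when using counts)
#' @param radius_fluct logical per instance (or NULL)
#' @param counts optional list(total =, myosin =, both =) of pre-tallied
#'   counts (e.g. from a published table); overrides the logical vectors
#' @return list with `pct_myosin_fluct`, `pct_radius_given_myosin`, and
#'   `counts` (total, myosin, both); percentages are NA when their
#'   denominator is zero
#' @export
fluctuation_fractions <- function(myosin_fluct = NULL, radius_fluct = NULL,
                                  counts = NULL) {
  if (is.null(counts)) {
    keep <- !is.na(myosin_fluct)
    m <- myosin_fluct[keep]
    r <- if (is.null(radius_fluct)) rep(FALSE, length(m)) else
      radius_fluct[keep] %in% TRUE
    counts <- list(total = length(m), myosin = sum(m), both = sum(m & r))
  }
  stopifnot(counts$myosin <= counts$total, counts$both <= counts$myosin)
  pct1 <- if (counts$total > 0) 100 * counts$myosin / counts$total else NA_real_
  pct2 <- if (counts$myosin > 0) 100 * counts$both / counts$myosin else NA_real_
  list(pct_myosin_fluct = pct1, pct_radius_given_myosin = pct2,
       counts = counts)
}

#' Phase-averaged myosin and inverse-radius signals with lead estimation
#'
#' Pools instances of all myosin cycles into phase bins over [0, 1), averages
#' the detrended myosin and detrended inverse radius per bin (with 1.96 SEM
#' confidence intervals), and estimates the lead of myosin over the inverse
#' radius as the circular difference of the two bin-mean curves' first-
#' harmonic phases, in cycles (positive = myosin ahead).
#'
#' @param phase per-instance myosin-cycle phase in [0, 1) (NA outside cycles)
#' @param detrended_myosin,detrended_inv_radius per-instance detrended signals
#' @param n_bins number of phase bins (>= 4; default 20)
#' @return list with `bins` (data.frame: phase_bin_lo, phase_bin_hi,
#'   mean_myosin, ci_lo_myosin, ci_hi_myosin, mean_inv_radius,
#'   ci_lo_inv_radius, ci_hi_inv_radius, n) and `lead_cycles` in [-0.5, 0.5)
#' @export
phase_average <- function(phase, detrended_myosin, detrended_inv_radius,
                          n_bins = 20) {
  if (n_bins < 4) stop("n_bins must be >= 4")
  keep <- !is.na(phase) & !is.na(detrended_myosin) & !is.na(detrended_inv_radius)
  ph <- phase[keep] %% 1
  m <- detrended_myosin[keep]; ir <- detrended_inv_radius[keep]
  bin <- pmin(floor(ph * n_bins), n_bins - 1) + 1
  stat <- function(v) {
    mn <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
    sem <- tapply(v, factor(bin, levels = seq_len(n_bins)), function(z)
      if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else 0)
    list(mean = as.vector(mn), sem = as.vector(sem))
  }
  sm <- stat(m); sr <- stat(ir)
  n <- as.vector(table(factor(bin, levels = seq_len(n_bins))))
  bins <- data.frame(
    phase_bin_lo = (seq_len(n_bins) - 1) / n_bins,
    phase_bin_hi = seq_len(n_bins) / n_bins,
    mean_myosin = sm$mean, ci_lo_myosin = sm$mean - 1.96 * sm$sem,
    ci_hi_myosin = sm$mean + 1.96 * sm$sem,
    mean_inv_radius = sr$mean, ci_lo_inv_radius = sr$mean - 1.96 * sr$sem,
    ci_hi_inv_radius = sr$mean + 1.96 * sr$sem, n = n)
  ctr <- (bins$phase_bin_lo + bins$phase_bin_hi) / 2
  # count-weighted first harmonic: equivalent to an instance-level fit, so
  # sparsely populated bins (phase sampling is quantized at ~7-8 instances
  # per cycle) cannot dominate the estimate
  harm_phase <- function(v) {
    ok <- !is.na(v) & n > 0
    Arg(sum(n[ok] * v[ok] * exp(2i * pi * ctr[ok]))) / (2 * pi)
  }
  lead <- (harm_phase(bins$mean_inv_radius) - harm_phase(bins$mean_myosin)) %% 1
  if (lead >= 0.5) lead <- lead - 1
  list(bins = bins, lead_cycles = lead)
}

#' Fraction of points with a nearby partner (focus colocalization)
#'
#' @param points_a,points_b n x 2 matrices, um
#' @param radius_um colocalization radius, um (> 0)
#' @return fraction of a-points with at least one b-point within radius; NA
#'   when `points_a` is empty
#' @export
focus_colocalization <- function(points_a, points_b, radius_um) {
  if (radius_um <= 0) stop("radius_um must be positive")
  if (is.null(points_a) || nrow(points_a) == 0) return(NA_real_)
  if (is.null(points_b) || nrow(points_b) == 0) return(0)
  hit <- vapply(seq_len(nrow(points_a)), function(i) {
    d2 <- (points_b[, 1] - points_a[i, 1])^2 +
          (points_b[, 2] - points_a[i, 2])^2
    any(d2 <= radius_um^2)
  }, TRUE)
  mean(hit)
}
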