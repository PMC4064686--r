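#' Oscillation parameters for synthetic placode dynamics
#'
#' Defaults emulate the pulsatile regime reported for the salivary-gland
#' placode: myosin cycle lengths of roughly 120-180 s, with the inverse apical
#' radius trailing medial myosin by about one-eighth of a cycle.
#'
#' @param period_mean mean oscillation period, s
#' @param period_sd between-cell period standard deviation, s
#' @param myosin_amplitude peak-to-peak medial myosin modulation, grayscale
#' @param myosin_baseline resting medial myosin level, grayscale
#' @param lag_cycles fraction of a cycle by which the (inverse-)radius response
#'   trails myosin, in [0, 1)
#' @param constriction_gain peak constriction rate per unit myosin modulation,
#'   um^2 per grayscale per min
#' @param radial_gradient dimensionless decay of oscillation activity with
#'   radial distance from the pit (0 = uniform, 1 = zero at the placode rim)
#' @param ratchet_fraction fraction of each constriction pulse retained after
#'   the pulse relaxes, in [0, 1]
#' @return list of class `oscillation_params`
#' @export
oscillation_params <- function(period_mean = 150, period_sd = 10,
                               myosin_amplitude = 5, myosin_baseline = 10,
                               lag_cycles = 0.125, constriction_gain = 0.5,
                               radial_gradient = 0.5, ratchet_fraction = 0.3) {
  stopifnot(period_mean > 0, period_sd >= 0,
            lag_cycles >= 0, lag_cycles < 1,
            ratchet_fraction >= 0, ratchet_fraction <= 1)
  structure(as.list(environment()), class = "oscillation_params")
}

# Raised-cosine pulse: smooth, one peak per cycle, in [0, 1], trough at phase 0.
osc_wave <- function(phase) (1 - cos(2 * pi * phase)) / 2

# Continuous-time truth for one cell: myosin (gs) and apical area (um^2).
# area modulation is proportional to the lagged myosin oscillation so that the
# inverse radius trails myosin by exactly lag_cycles; constriction_gain sets
# the peak oscillatory constriction rate (um^2/min). The ratchet accumulates
# continuously at ratchet_fraction of one pulse depth per elapsed cycle.
cell_truth_fun <- function(area0, period, phase0, scale, params) {
  amp_m <- params$myosin_amplitude * scale
  # peak |dA/dt| of c*osc(phase(t)) is c*pi/period_s per s = c*60*pi/period per min
  c_area <- params$constriction_gain * amp_m * period / (60 * pi)
  # small apices cannot constrict by more than a fraction of their own area
  c_area <- min(c_area, 0.2 * area0)
  list(
    myosin = function(t) params$myosin_baseline +
      amp_m * osc_wave(phase0 + t / period),
    area = function(t) area0 -
      c_area * osc_wave(phase0 + t / period - params$lag_cycles) -
      params$ratchet_fraction * c_area * (t / period),
    phase = function(t) (phase0 + t / period) %% 1,
    c_area = c_area, amp_m = amp_m, period = period, phase0 = phase0
  )
}

#' Simulate pulsatile constriction dynamics on an epithelium
#'
#' Each placodal cell oscillates with its own period (drawn from
#' N(period_mean, period_sd^2)) and random initial phase; oscillation
#' amplitude decays with radial distance from the pit. Apical area is
#' modulated by the lagged myosin oscillation plus a ratchet term, and the
#' net placodal area loss is compensated by growth of the non-placodal margin
#' cells so the tiling conserves total area. Cell polygons are realized on the
#' shared-vertex mesh by iterative relaxation, keeping the tiling conforming.
#'
#' @param geom an `epithelium` from [generate_epithelium()]
#' @param params an `oscillation_params`
#' @param frame_interval s between frames (default 20 s)
#' @param duration total simulated time, s; must be >= 2 * period_mean
#' @param seed integer RNG seed
#' @return a `dynamics_truth` object: list with `truth` (data.frame: cell_id,
#'   frame, t_s, area_um2, radius_um, myosin_true, phase_true, placode_flag),
#'   `vertices` (list of per-frame vertex matrices), `geom`, `params`,
#'   `cell_funs` (continuous-time truth closures), `times`, `seed`.
#' @export
simulate_dynamics <- function(geom, params = oscillation_params(),
                              frame_interval = 20, duration = 900,
                              seed = 1L) {
  stopifnot(inherits(geom, "epithelium"), frame_interval > 0)
  if (duration < 2 * params$period_mean)
    stop("duration must cover at least two mean periods")
  set.seed(seed)
  n <- length(geom$cells)
  polys <- epithelium_polygons(geom)
  area0 <- vapply(polys, poly_area, 0)
  cents <- t(vapply(polys, poly_centroid, c(0, 0)))
  r <- sqrt((cents[, 1] - geom$pit_center[1])^2 +
            (cents[, 2] - geom$pit_center[2])^2)
  r_ref <- max(r[geom$placode_mask], 1e-9)
  scale <- pmax(0, 1 - params$radial_gradient * r / r_ref)
  scale[!geom$placode_mask] <- 0          # margin cells do not pulse

  periods <- pmax(params$period_mean / 4,
                  stats::rnorm(n, params$period_mean, params$period_sd))
  phases0 <- stats::runif(n)

  cell_funs <- lapply(seq_len(n), function(i)
    cell_truth_fun(area0[i], periods[i], phases0[i], scale[i], params))

  times <- seq(0, duration, by = frame_interval)
  target <- vapply(cell_funs, function(f) f$area(times), numeric(length(times)))
  if (any(target <= 0.5))
    stop("parameters drive cell areas to (near) zero within duration; ",
         "reduce constriction_gain, ratchet_fraction or duration")
  # Conservation: distribute placodal loss over margin cells, area-weighted.
  tot0 <- sum(area0)
  marg <- !geom$placode_mask
  if (any(marg)) {
    deficit <- tot0 - rowSums(target)
    wts <- area0[marg] / sum(area0[marg])
    target[, marg] <- target[, marg] + outer(deficit, wts)
  }

  vertices <- vector("list", length(times))
  v <- geom$vertices
  mi <- build_mesh_index(geom)
  for (k in seq_along(times)) {
    v <- realize_areas(geom, target[k, ], n_iter = if (k == 1) 80 else 30,
                       vertices = v, mesh_index = mi)
    vertices[[k]] <- v
  }

  truth <- data.frame(
    cell_id = rep(seq_len(n), each = length(times)),
    frame = rep(seq_along(times), n),
    t_s = rep(times, n),
    area_um2 = as.vector(target),
    radius_um = sqrt(as.vector(target) / pi),
    myosin_true = as.vector(vapply(cell_funs, function(f) f$myosin(times),
                                   numeric(length(times)))),
    phase_true = as.vector(vapply(cell_funs, function(f) f$phase(times),
                                  numeric(length(times)))),
    placode_flag = rep(geom$placode_mask, each = length(times))
  )

  structure(list(truth = truth, vertices = vertices, geom = geom,
                 params = params, cell_funs = cell_funs, times = times,
                 seed = seed),
            class = "dynamics_truth")
}

#' @export
print.dynamics_truth <- function(x, ...) {
  cat(sprintf("dynamics_truth: %d cells x %d frames (dt %.0f s, %.0f s total)\n",
              length(x$geom$cells), length(x$times), diff(x$times[1:2]),
              max(x$times)))
  invisible(x)
}

#' Generate a fixed-frame placode with a chosen spatial pattern of apical areas
#'
#' The two patterns share the same multiset of target cell areas (for a fixed
#' seed) but arrange them differently: `wildtype_gradient` places the smallest
#' apices nearest the pit (clustered constriction), `dispersed` scatters them
#' uniformly (the microtubule-depleted phenotype).
#'
#' @param pattern "wildtype_gradient" or "dispersed"
#' @param n_cells number of cells (>= 20)
#' @param seed integer RNG seed
#' @param domain domain size, um
#' @param spread peak-to-trough relative area contrast of the pattern
#' @return list with `geom` (vertices realized to the pattern), `truth`
#'   (data.frame: cell_id, area_um2, r_um, placode_flag), `pattern`
#' @export
make_fixed_placode <- function(pattern = c("wildtype_gradient", "dispersed"),
                               n_cells = 150, seed = 1L, domain = c(80, 80),
                               spread = 0.6) {
  pattern <- match.arg(pattern)
  stopifnot(n_cells >= 20)
  geom <- generate_epithelium(n_cells, domain, jitter = 0.25, seed = seed)
  polys <- epithelium_polygons(geom)
  area0 <- vapply(polys, poly_area, 0)
  cents <- t(vapply(polys, poly_centroid, c(0, 0)))
  r <- sqrt((cents[, 1] - geom$pit_center[1])^2 +
            (cents[, 2] - geom$pit_center[2])^2)
  set.seed(seed + 1L)
  # one multiset of multiplicative factors, shared by both patterns
  fac <- sort(stats::runif(n_cells, 1 - spread / 2, 1 + spread / 2))
  ord <- switch(pattern,
    # smallest factors nearest the pit, with mild biological scatter
    wildtype_gradient = order(r + stats::rnorm(n_cells, 0, 0.12 * max(r))),
    dispersed = sample.int(n_cells))
  factors <- numeric(n_cells)
  factors[ord] <- fac
  target <- mean(area0) * factors
  target <- target * sum(area0) / sum(target)
  # anneal toward the target pattern so large area contrasts stay realizable
  v <- geom$vertices
  mi <- build_mesh_index(geom)
  for (stage in seq(0.25, 1, by = 0.25)) {
    v <- realize_areas(geom, (1 - stage) * area0 + stage * target,
                       n_iter = 60, vertices = v, mesh_index = mi)
  }
  geom$vertices <- v
  truth <- data.frame(cell_id = seq_len(n_cells), area_um2 = target,
                      r_um = r, placode_flag = geom$placode_mask)
  list(geom = geom, truth = truth, pattern = pattern)
}
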