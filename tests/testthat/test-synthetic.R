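test_that("a single-cell epithelium is the domain rectangle with no neighbors", {
  g <- generate_epithelium(1, c(30, 20))
  expect_equal(poly_area(epithelium_polygons(g)[[1]]), 600)
  expect_equal(nrow(g$adjacency), 0)
})

test_that("an unjittered lattice yields equal-area interior hexagons", {
  g <- generate_epithelium(100, c(80, 80), jitter = 0, seed = 1)
  a <- vapply(epithelium_polygons(g), poly_area, 0)
  # interior cells are exact regular hexagons; boundary cells absorb the rest
  expect_gte(max(table(round(a, 6))), 50)
})

test_that("cell polygons partition the domain for any seed and jitter", {
  for (sd_ in 1:4) {
    g <- generate_epithelium(120, c(70, 60), jitter = 0.25, seed = sd_)
    a <- vapply(epithelium_polygons(g), poly_area, 0)
    expect_equal(sum(a), 70 * 60, tolerance = 1e-6)
    expect_length(a, 120)
    # adjacency is symmetric-by-construction and edge-induced
    expect_true(all(g$adjacency[, 1] != g$adjacency[, 2]))
  }
})

test_that("degenerate domains and overfilled domains are rejected", {
  expect_error(generate_epithelium(10, c(-5, 10)), "positive")
  expect_error(generate_epithelium(10000, c(10, 10)), "pitch")
})

test_that("geometry generation is deterministic in the seed", {
  g1 <- generate_epithelium(50, seed = 3)
  g2 <- generate_epithelium(50, seed = 3)
  expect_identical(g1$vertices, g2$vertices)
  expect_identical(g1$cells, g2$cells)
})

test_that("zero myosin amplitude freezes all cell areas", {
  g <- small_geom()
  dyn <- simulate_dynamics(g, oscillation_params(myosin_amplitude = 0),
                           duration = 600, seed = 1)
  rng <- tapply(dyn$truth$area_um2, dyn$truth$cell_id,
                function(a) diff(range(a)))
  expect_equal(max(rng), 0)
})

test_that("20 s frames over 900 s give 46 frames including t = 0", {
  dyn <- simulate_dynamics(small_geom(), frame_interval = 20, duration = 900,
                           seed = 2)
  expect_equal(length(dyn$times), 46)
  expect_equal(max(dyn$truth$frame), 46)
})

test_that("myosin-to-area lag on dense continuous truth equals lag_cycles", {
  g <- small_geom()
  p <- oscillation_params(period_sd = 0, lag_cycles = 0.125)
  dyn <- simulate_dynamics(g, p, duration = 900, seed = 3)
  ids <- which(g$placode_mask)[1:5]
  for (i in ids) {
    f <- dyn$cell_funs[[i]]
    dt <- f$period / round(f$period)           # ~1 s, whole cycles exactly
    ts <- seq(0, 4 * f$period, by = dt)
    # first differences kill the linear ratchet drift exactly while leaving
    # the oscillation's phase untouched (a linear fit would not: its slope
    # on a cosine segment depends on the starting phase)
    m <- diff(f$myosin(ts))
    negA <- diff(-f$area(ts))
    m <- m - mean(m); negA <- negA - mean(negA)
    lags <- 0:60
    cc <- vapply(lags, function(l)            # circular cross-correlation
      stats::cor(m, negA[(seq_along(negA) + l - 1) %% length(negA) + 1]), 0)
    k <- which.max(cc)
    best <- lags[k]
    if (k > 1 && k < length(cc))   # parabolic sub-sample refinement
      best <- best + 0.5 * (cc[k - 1] - cc[k + 1]) /
        (cc[k - 1] - 2 * cc[k] + cc[k + 1])
    expect_equal(best * dt, 0.125 * f$period, tolerance = 0.02)
  }
})

test_that("inverse-radius truth trails myosin by lag_cycles when periods are equal", {
  g <- small_geom()
  for (lag in c(0, 0.125, 0.3)) {
    p <- oscillation_params(period_sd = 0, lag_cycles = lag)
    dyn <- simulate_dynamics(g, p, duration = 900, seed = 4)
    f <- dyn$cell_funs[[which(g$placode_mask)[3]]]
    ts0 <- seq(0, 5 * f$period, by = 0.5)        # whole cycles
    # differencing removes the ratchet drift and shifts both signals by the
    # same transfer phase, leaving their phase difference intact
    m <- diff(f$myosin(ts0)); invr <- diff(1 / sqrt(f$area(ts0) / pi))
    ts <- ts0[-1]
    # circular phase of the fundamental at the known period
    # Arg(sum x e^{-iwt}) returns minus the delay phase, so the signal that
    # lags has the smaller Arg: myosin minus inverse radius gives the lag
    ph <- function(x) Arg(sum(x * exp(-2i * pi * ts / f$period)))
    d <- ((ph(m) - ph(invr)) / (2 * pi)) %% 1
    expect_lt(min(abs(d - lag), abs(d - lag + 1), abs(d - lag - 1)), 0.01)
  }
})

test_that("total tissue area is conserved at every frame", {
  dyn <- small_dynamics()
  tot <- tapply(dyn$truth$area_um2, dyn$truth$frame, sum)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 0.005)
  # realized polygons also partition the domain
  a <- vapply(epithelium_polygons(dyn$geom, dyn$vertices[[20]]), poly_area, 0)
  expect_equal(sum(a), prod(dyn$geom$domain), tolerance = 1e-6)
})

test_that("unrealizable constriction parameters are rejected with a diagnostic", {
  g <- small_geom()
  expect_error(
    simulate_dynamics(g, oscillation_params(constriction_gain = 500,
                                            ratchet_fraction = 1),
                      duration = 1200, seed = 1),
    "reduce")
})

test_that("noise-free flat-surface render paints membrane only on boundary pixels of the shell slice", {
  dyn <- small_dynamics()
  opt <- render_optics(surface_height = 3, psf_sigma = 0,
                       photon_noise_scale = 0, background = 0)
  mov <- render_movie(dyn, opt, seed = 1)
  sl <- mov$intensities[1, 4, 1, , ]                 # z = 3 um -> slice 4
  bnd <- mov$labels_truth[1, , ] == 0
  expect_true(all((sl > 0) == bnd))
  expect_equal(sum(mov$intensities[1, -4, 1, , ]), 0)
})

test_that("re-measured medial myosin matches truth after background subtraction", {
  dyn <- small_dynamics()
  opt <- render_optics(surface_height = 3, psf_sigma = 0,
                       photon_noise_scale = 0)
  mov <- render_movie(dyn, opt, seed = 1)
  lab <- mov$labels_truth[5, , ]
  myo <- mov$intensities[5, 4, 2, , ] - mov$optics$background
  dist <- t(as.matrix(EBImage::distmap(t(lab > 0))))
  medial <- lab > 0 & dist > mov$optics$band_width_um / mov$px_size_um
  meas <- tapply(myo[medial], lab[medial], mean)
  tr <- dyn$truth[dyn$truth$frame == 5, ]
  truth_vals <- tr$myosin_true[as.integer(names(meas))]
  expect_lt(max(abs(meas - truth_vals) / truth_vals), 0.01)
})

test_that("rendering is bit-reproducible for a fixed seed", {
  dyn <- small_dynamics()
  m1 <- render_movie(dyn, render_optics(), seed = 5)
  m2 <- render_movie(dyn, render_optics(), seed = 5)
  expect_identical(m1$intensities, m2$intensities)
})

test_that("surfaces leaving the stack or too steep are rejected", {
  dyn <- small_dynamics()
  expect_error(render_movie(dyn, render_optics(surface_height = 50), seed = 1),
               "z range")
  steep <- function(x, y) 4 + 4 * sin(x * 3)
  expect_error(render_movie(dyn, render_optics(surface_height = steep),
                            seed = 1), "steep")
})

test_that("fixed-placode patterns share an area multiset but differ in arrangement", {
  wt <- make_fixed_placode("wildtype_gradient", 120, seed = 5)
  dp <- make_fixed_placode("dispersed", 120, seed = 5)
  expect_equal(sort(wt$truth$area_um2), sort(dp$truth$area_um2))
  rho_wt <- stats::cor(wt$truth$area_um2, wt$truth$r_um, method = "spearman")
  rho_dp <- stats::cor(dp$truth$area_um2, dp$truth$r_um, method = "spearman")
  expect_gt(rho_wt, 0.5)
  expect_lt(abs(rho_dp), 0.15)
})

test_that("movies round-trip through TIFF + JSON sidecar", {
  dyn <- small_dynamics()
  mov <- render_movie(dyn, render_optics(photon_noise_scale = 0), seed = 1)
  tf <- tempfile(fileext = ".tif")
  write_movie_tiff(mov, tf)
  back <- read_movie_tiff(tf)
  expect_equal(dim(back$intensities), dim(mov$intensities))
  expect_equal(back$intensities, mov$intensities, tolerance = 1e-4)
  expect_equal(back$frame_interval_s, 20)
  unlink(c(tf, paste0(tf, ".json"), sub("\\.tif$", "_truth.csv", tf)))
})
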