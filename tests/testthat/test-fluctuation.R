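test_that("region partition offsets squares exactly", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  pr <- partition_regions(sq, 1)
  expect_equal(pr$medial_area_um2, 64)
  expect_equal(pr$junctional_area_um2, 36)
  pr0 <- partition_regions(sq, 0)
  expect_equal(pr0$medial_area_um2, 100)
  expect_equal(pr0$junctional_area_um2, 0)
  expect_error(partition_regions(sq, -1), ">= 0")
})

test_that("medial and junctional areas always sum to the cell area", {
  set.seed(1)
  for (i in 1:20) {
    th <- sort(stats::runif(7, 0, 2 * pi))
    p <- cbind(5 * cos(th), 5 * sin(th)) + 10
    pr <- partition_regions(p, stats::runif(1, 0, 2))
    expect_equal(pr$medial_area_um2 + pr$junctional_area_um2,
                 poly_area(p), tolerance = 1e-9)
  }
})

test_that("a deep offset empties the medial region gracefully", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  pr <- partition_regions(sq, 5)
  expect_null(pr$medial)
  expect_equal(pr$junctional_area_um2, 4)
})

test_that("boxcar detrending removes constants and interior ramps exactly", {
  t <- seq(0, 900, 20)
  d <- detrend(rep(3.2, length(t)), t)
  expect_true(all(d$detrended == 0))
  d2 <- detrend(0.05 * t, t)
  interior <- t >= 180 & t <= 720
  expect_equal(max(abs(d2$detrended[interior])), 0, tolerance = 1e-12)
})

test_that("trend plus detrended reconstructs the raw trace bit-exactly", {
  set.seed(2)
  t <- seq(0, 600, 20)
  x <- stats::rnorm(length(t), 10, 2)
  d <- detrend(x, t)
  expect_identical(d$trend + d$detrended, d$raw)
  expect_error(detrend(x, t, window_s = 10), "frame intervals")
})

test_that("a 360 s boxcar keeps most of a 150 s oscillation", {
  t <- seq(0, 900, 20)
  x <- sin(2 * pi * t / 150)
  d <- detrend(x, t)
  interior <- t >= 180 & t <= 720
  expect_gte(max(abs(d$detrended[interior])), 0.8)
})

test_that("cycles of a pure sinusoid have the right length and amplitude", {
  t <- seq(0, 900, 20)
  a <- 1.7
  x <- a * sin(2 * pi * t / 150)
  cyc <- detect_cycles(x, t, "myosin", locate_smooth = 1, amp_smooth = 1)
  expect_gt(nrow(cyc), 2)
  expect_true(all(abs(cyc$length_s - 150) <= 20))
  expect_true(all(abs(cyc$amplitude - 2 * a) <= 2 * a * 0.15))
  # radius cycles anchor on peaks instead of troughs
  cycr <- detect_cycles(x, t, "radius", locate_smooth = 1, amp_smooth = 1)
  expect_true(all(abs(cycr$length_s - 150) <= 20))
  expect_false(any(cyc$start_s %in% cycr$start_s))
})

test_that("monotonic traces contain no cycles", {
  t <- seq(0, 380, 20)
  expect_equal(nrow(detect_cycles(seq_along(t), t, "myosin")), 0)
  expect_equal(nrow(detect_cycles(rep(1, length(t)), t, "myosin")), 0)
})

test_that("detected cycles are disjoint, ordered, and phase-complete", {
  set.seed(3)
  t <- seq(0, 1200, 20)
  x <- sin(2 * pi * t / 140) + 0.2 * stats::rnorm(length(t))
  cyc <- detect_cycles(x, t, "myosin")
  expect_true(all(diff(cyc$start_s) > 0))
  expect_true(all(cyc$end_s[-nrow(cyc)] == cyc$start_s[-1]))
  ph <- cycle_phase(t, cyc)
  inside <- !is.na(ph$phase)
  expect_true(all(ph$phase[inside] >= 0 & ph$phase[inside] < 1))
  # each instance maps to at most one cycle
  expect_true(all(table(ph$cycle_id[inside], t[inside]) <= 1))
})

test_that("activity classification applies the amplitude x frequency rule", {
  cyc <- data.frame(cycle = 1L, start_s = 0, end_s = 150, length_s = 150,
                    amplitude = 1.5, start_idx = 1L, end_idx = 8L)
  ca <- classify_activity(75, cyc, threshold = 0.5)
  expect_equal(ca$activity, 0.6)      # 1.5 * (60/150)
  expect_true(ca$fluctuating)
  cyc$amplitude <- 0.5; cyc$length_s <- 300; cyc$end_s <- 300
  ca2 <- classify_activity(75, cyc, threshold = 0.5)
  expect_equal(ca2$activity, 0.1)
  expect_false(ca2$fluctuating)
  # outside any cycle: non-fluctuating, NA activity
  ca3 <- classify_activity(400, cyc, threshold = 0.5)
  expect_true(is.na(ca3$activity) && !ca3$fluctuating)
  expect_error(classify_activity(75, cyc, threshold = 0), "positive")
})

test_that("raising the threshold never adds fluctuating instances", {
  set.seed(4)
  t <- seq(0, 1200, 20)
  x <- sin(2 * pi * t / 150) * stats::runif(length(t), 0.5, 1.5)
  cyc <- detect_cycles(x, t, "myosin")
  counts <- vapply(seq(0.05, 1, length.out = 20), function(thr)
    sum(classify_activity(t, cyc, thr)$fluctuating), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("pooled fractions reproduce published-style count arithmetic", {
  wt <- fluctuation_fractions(counts = list(total = 2877, myosin = 1849,
                                            both = 929))
  expect_equal(round(wt$pct_myosin_fluct), 64)
  mt <- fluctuation_fractions(counts = list(total = 3711, myosin = 1584,
                                            both = 1106))
  expect_equal(round(mt$pct_myosin_fluct), 43)
  # conditional numerators can never exceed their denominators
  expect_lte(wt$counts$both, wt$counts$myosin)
  none <- fluctuation_fractions(myosin_fluct = c(FALSE, FALSE),
                                radius_fluct = c(FALSE, FALSE))
  expect_equal(none$pct_myosin_fluct, 0)
  expect_true(is.na(none$pct_radius_given_myosin))
})

test_that("phase averaging matches a brute-force pool-and-average oracle", {
  set.seed(5)
  n <- 400
  ph <- stats::runif(n)
  m <- sin(2 * pi * ph) + 0.1 * stats::rnorm(n)
  ir <- cos(2 * pi * ph) + 0.1 * stats::rnorm(n)
  pa <- phase_average(ph, m, ir, n_bins = 10)
  bin <- pmin(floor(ph * 10), 9) + 1
  for (b in 1:10) {
    expect_equal(pa$bins$mean_myosin[b], mean(m[bin == b]), tolerance = 1e-12)
    expect_equal(pa$bins$mean_inv_radius[b], mean(ir[bin == b]),
                 tolerance = 1e-12)
  }
  expect_error(phase_average(ph, m, ir, n_bins = 3), "n_bins")
})

test_that("phase averaging recovers known imposed leads", {
  set.seed(6)
  n <- 3000
  ph <- stats::runif(n)
  for (lag in c(0, 0.125, 0.25)) {
    m <- -cos(2 * pi * ph) + 0.05 * stats::rnorm(n)
    ir <- -cos(2 * pi * (ph - lag)) + 0.05 * stats::rnorm(n)
    pa <- phase_average(ph, m, ir)
    expect_equal(pa$lead_cycles, lag, tolerance = 0.02)
  }
})

test_that("focus colocalization has the right degenerate limits", {
  set.seed(7)
  a <- cbind(stats::runif(30, 0, 20), stats::runif(30, 0, 20))
  expect_equal(focus_colocalization(a, a, 0.5), 1)
  expect_equal(focus_colocalization(a, a[0, , drop = FALSE], 0.5), 0)
  expect_true(is.na(focus_colocalization(a[0, , drop = FALSE], a, 0.5)))
  expect_error(focus_colocalization(a, a, 0), "positive")
})

test_that("random-point colocalization matches the Poisson null", {
  # fraction ~ 1 - exp(-lambda * pi * r^2) for uniform b-points
  L <- 50; nb <- 200; r <- 1.5
  lambda <- nb / L^2
  expected <- 1 - exp(-lambda * pi * r^2)
  fracs <- vapply(1:100, function(s) {
    set.seed(s)
    a <- cbind(stats::runif(60, 5, L - 5), stats::runif(60, 5, L - 5))
    b <- cbind(stats::runif(nb, 0, L), stats::runif(nb, 0, L))
    focus_colocalization(a, b, r)
  }, 0)
  se <- stats::sd(fracs) / 10
  expect_lt(abs(mean(fracs) - expected), 3 * se + 0.02)
})
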