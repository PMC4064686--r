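test_that("polygon geometry matches closed forms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- measure_geometry(sq)
  expect_equal(m$area_um2, 1)
  expect_equal(m$radius_um, sqrt(1 / pi), tolerance = 1e-6)
  # regular hexagon, side 2: area (3*sqrt(3)/2) * s^2
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hx <- cbind(2 * cos(th), 2 * sin(th))
  expect_equal(measure_geometry(hx)$area_um2, 3 * sqrt(3) / 2 * 4,
               tolerance = 1e-9)
})

test_that("area and radius are translation invariant", {
  set.seed(2)
  th <- sort(stats::runif(8, 0, 2 * pi))
  p <- cbind(3 * cos(th), 3 * sin(th))
  m1 <- measure_geometry(p)
  m2 <- measure_geometry(sweep(p, 2, c(17.3, -4.2), "+"))
  expect_equal(m1$area_um2, m2$area_um2)
  expect_equal(m1$radius_um, m2$radius_um)
})

test_that("self-intersecting polygons are rejected", {
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(measure_geometry(bow), "self-intersect")
})

test_that("the centroid-to-vertex radius convention is available", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circle <- cbind(2 * cos(th), 2 * sin(th))
  m <- measure_geometry(circle, radius_mode = "centroid_vertex_mean")
  expect_equal(m$radius_um, 2, tolerance = 1e-9)
})

test_that("neighbor dispersion reproduces the hand-worked three-cell case", {
  adj <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  D <- neighbor_dispersion(areas = c(10, 12, 20), adjacency = adj)
  expect_equal(D$D_um2, c((2 + 10) / 2, (2 + 8) / 2, (10 + 8) / 2))
})

test_that("dispersion is zero iff all neighbors share the cell's area", {
  adj <- rbind(c(1L, 2L), c(2L, 3L))
  D <- neighbor_dispersion(areas = c(5, 5, 5), adjacency = adj)
  expect_equal(D$D_um2, c(0, 0, 0))
})

test_that("dispersion from a label image matches a brute-force oracle", {
  set.seed(4)
  mov <- small_movie_clean()
  lab <- mov$labels_truth[1, , ]
  areas <- tabulate(lab[lab > 0]) * mov$px_size_um^2
  D <- neighbor_dispersion(lab, areas)
  # independent brute force: scan all pixel pairs at distance <= 3
  nb <- list()
  for (i in seq_len(max(lab))) nb[[i]] <- integer(0)
  ny <- nrow(lab); nx <- ncol(lab)
  for (d in 1:3) {
    for (pair in list(cbind(as.vector(lab[seq_len(ny - d), ]),
                            as.vector(lab[seq_len(ny - d) + d, ])),
                      cbind(as.vector(lab[, seq_len(nx - d)]),
                            as.vector(lab[, seq_len(nx - d) + d])))) {
      ok <- pair[, 1] > 0 & pair[, 2] > 0 & pair[, 1] != pair[, 2]
      for (r in which(ok)) {
        nb[[pair[r, 1]]] <- c(nb[[pair[r, 1]]], pair[r, 2])
        nb[[pair[r, 2]]] <- c(nb[[pair[r, 2]]], pair[r, 1])
      }
    }
  }
  D2 <- vapply(seq_len(max(lab)), function(i) {
    js <- unique(nb[[i]])
    if (!length(js)) return(NA_real_)
    mean(abs(areas[i] - areas[js]))
  }, 0)
  expect_gt(sum(!is.na(D2)), max(lab) / 2)   # guard against a vacuous pass
  expect_equal(D$D_um2, D2)
})

test_that("dispersion is invariant under label permutation", {
  mov <- small_movie_clean()
  lab <- mov$labels_truth[1, , ]
  n <- max(lab)
  areas <- tabulate(lab[lab > 0]) * mov$px_size_um^2
  set.seed(5)
  perm <- sample.int(n)
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  areas2 <- numeric(n); areas2[perm] <- areas
  D1 <- neighbor_dispersion(lab, areas)
  D2 <- neighbor_dispersion(lab2, areas2)
  expect_equal(D1$D_um2, D2$D_um2[perm])
})

test_that("placode coordinates follow the pit-centered convention", {
  co <- assign_placode_coordinates(c(10, 13), c(20, 24), pit_center = c(10, 20))
  expect_equal(co$r_um, c(0, 5))
  expect_equal(co$anterior_um, c(0, -3))
  expect_equal(co$ventral_um, c(0, -4))
  expect_error(assign_placode_coordinates(1, 1, NULL), "pit_center")
})

test_that("radial distance is invariant under rotation about the pit", {
  set.seed(6)
  x <- stats::runif(20, 0, 50); y <- stats::runif(20, 0, 50)
  pit <- c(25, 25)
  th <- 0.7
  xr <- pit[1] + cos(th) * (x - pit[1]) - sin(th) * (y - pit[2])
  yr <- pit[2] + sin(th) * (x - pit[1]) + cos(th) * (y - pit[2])
  expect_equal(assign_placode_coordinates(x, y, pit)$r_um,
               assign_placode_coordinates(xr, yr, pit)$r_um)
})

test_that("radial profile matches a brute-force group-by oracle", {
  set.seed(7)
  r <- stats::runif(500, 0, 42)
  v <- stats::rnorm(500, mean = r)
  rp <- radial_profile(v, r, bin_width_um = 5)
  for (b in seq_len(nrow(rp))) {
    sel <- r >= rp$bin_lo[b] & r < rp$bin_hi[b]
    expect_equal(rp$n[b], sum(sel))
    if (any(sel)) {
      expect_equal(rp$mean[b], mean(v[sel]), tolerance = 1e-12)
      sem <- stats::sd(v[sel]) / sqrt(sum(sel))
      if (sum(sel) > 1) expect_equal(rp$ci_hi[b] - rp$mean[b], 1.96 * sem,
                                     tolerance = 1e-12)
    }
  }
  expect_equal(sum(rp$n), 500)
})

test_that("radial profile handles constants and identity values", {
  r <- c(1, 2, 22, 23, 24)
  rp <- radial_profile(rep(1, 5), r, 5)
  expect_true(all(rp$mean[rp$n > 0] == 1))
  expect_true(all((rp$ci_hi - rp$ci_lo)[rp$n > 0] == 0))
  rp2 <- radial_profile(r, r, 5)
  b <- which(rp2$bin_lo == 20)
  expect_gte(rp2$mean[b], 20); expect_lt(rp2$mean[b], 25)
  expect_error(radial_profile(1, 1, 0), "positive")
})

test_that("area-change rates recover linear inputs exactly", {
  t <- seq(0, 600, 20)
  const <- area_change_rate(t, rep(50, length(t)))
  expect_equal(max(abs(const$dA_dt_um2_min), na.rm = TRUE), 0)
  lin <- area_change_rate(t, 100 - t / 60)
  expect_equal(unique(round(stats::na.omit(lin$dA_dt_um2_min), 10)), -1)
})

test_that("area-change slope matches a normal-equations oracle", {
  set.seed(8)
  t <- seq(0, 600, 20)
  A <- 60 + cumsum(stats::rnorm(length(t)))
  out <- area_change_rate(t, A, window_s = 100)
  for (i in seq_along(t)) {
    w <- which(abs(t - t[i]) <= 50 + 1e-9)
    if (length(w) >= 3) {
      X <- cbind(1, t[w])
      beta <- solve(crossprod(X), crossprod(X, A[w]))
      expect_equal(out$dA_dt_um2_min[i], beta[2] * 60, tolerance = 1e-10)
    }
  }
})

test_that("area-change rate is linear in the input signal", {
  t <- seq(0, 400, 20)
  set.seed(9)
  a <- stats::runif(length(t), 40, 60)
  b <- stats::runif(length(t), 40, 60)
  ra <- area_change_rate(t, a)$dA_dt_um2_min
  rb <- area_change_rate(t, b)$dA_dt_um2_min
  rab <- area_change_rate(t, 2 * a + 3 * b)$dA_dt_um2_min
  expect_equal(rab, 2 * ra + 3 * rb, tolerance = 1e-9)
  expect_error(area_change_rate(t, a, window_s = 10), "frame intervals")
})
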