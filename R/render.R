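#' Optical model for synthetic movie rendering
#'
#' @param surface_height function(x_um, y_um) -> z_um (vectorized) giving the
#'   apical surface depth, or a single number for a flat surface. The default
#'   is a gentle dome dipping toward the invagination pit; its gradient stays
#'   below 1 um/um.
#' @param psf_sigma Gaussian point-spread sigma, um (0 disables blurring)
#' @param background additive background level, grayscale
#' @param photon_noise_scale scale of the Poisson photon noise (0 disables all
#'   noise, giving bit-reproducible renders); larger is noisier
#' @param read_noise_sd Gaussian read-noise sd, grayscale (applied only when
#'   photon_noise_scale > 0)
#' @param membrane_intensity cortex brightness painted on cell outlines
#' @param junctional_intensity myosin-channel brightness on cell outlines
#' @param band_width_um width of the junctional band; pixels farther than
#'   this from a cell outline carry the medial myosin signal
#' @return list of class `render_optics`
#' @export
render_optics <- function(surface_height = NULL, psf_sigma = 0.3,
                          background = 2, photon_noise_scale = 0.5,
                          read_noise_sd = 0.5,
                          membrane_intensity = 50, junctional_intensity = 8,
                          band_width_um = 0.6) {
  stopifnot(psf_sigma >= 0, photon_noise_scale >= 0)
  structure(as.list(environment()), class = "render_optics")
}

default_surface <- function(pit_center, z_depth) {
  force(pit_center); force(z_depth)
  function(x, y) {
    d2 <- (x - pit_center[1])^2 + (y - pit_center[2])^2
    pmin(z_depth - 1.5, 2 + 3 * exp(-d2 / (2 * 18^2)))
  }
}

# Rasterize cell polygons to a label image (rows = y, cols = x, um calibrated).
# Pixel centers at (i - 0.5) * px. Returns integer matrix; 0 = unassigned.
rasterize_cells <- function(polys, domain, px) {
  nx <- round(domain[1] / px); ny <- round(domain[2] / px)
  lab <- matrix(0L, ny, nx)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    cx <- which(xs >= min(p[, 1]) - px & xs <= max(p[, 1]) + px)
    cy <- which(ys >= min(p[, 2]) - px & ys <= max(p[, 2]) + px)
    if (!length(cx) || !length(cy)) next
    gx <- rep(xs[cx], each = length(cy))
    gy <- rep(ys[cy], times = length(cx))
    inside <- points_in_poly(gx, gy, p)
    sub <- lab[cy, cx]
    sub[inside & sub == 0L] <- i
    lab[cy, cx] <- sub
  }
  lab
}

# Membrane skeleton: pixels whose 4-neighborhood contains a different label.
label_boundaries <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  b <- matrix(FALSE, ny, nx)
  b[-ny, ] <- b[-ny, ] | (lab[-ny, ] != lab[-1, ])
  b[-1, ]  <- b[-1, ]  | (lab[-ny, ] != lab[-1, ])
  b[, -nx] <- b[, -nx] | (lab[, -nx] != lab[, -1])
  b[, -1]  <- b[, -1]  | (lab[, -nx] != lab[, -1])
  b
}

gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  EBImage::gblur(m, sigma = sigma_px)
}

#' Render a synthetic two-channel confocal movie from dynamics ground truth
#'
#' The membrane channel paints the cell-boundary skeleton in a thin shell at
#' the apical surface height; the myosin channel paints each cell's true
#' medial intensity inside its junctional band plus a junctional component on
#' the outlines. Optional Gaussian PSF blurring (lateral and axial) and scaled
#' Poisson + Gaussian read noise follow.
#'
#' @param truth a `dynamics_truth` from [simulate_dynamics()]
#' @param optics a `render_optics`
#' @param seed integer RNG seed for the noise
#' @param px_size_um lateral pixel size (um)
#' @param z_step_um axial step (um); default 1 um
#' @param n_slices number of z slices
#' @return a `synthetic_movie`: list with `intensities` (5D array t,z,c,y,x),
#'   `channels` = c("membrane","myosin"), `px_size_um`, `z_step_um`,
#'   `frame_interval_s`, `surface_truth` (t,y,x um), `labels_truth`
#'   (t,y,x integer cell ids; 0 on the skeleton), `truth` (the input tables).
#' @export
render_movie <- function(truth, optics = render_optics(), seed = 1L,
                         px_size_um = 0.4, z_step_um = 1, n_slices = 10) {
  stopifnot(inherits(truth, "dynamics_truth"))
  geom <- truth$geom
  sf <- optics$surface_height
  if (is.null(sf)) sf <- default_surface(geom$pit_center,
                                         (n_slices - 1) * z_step_um)
  if (is.numeric(sf) && length(sf) == 1) { zc <- sf; sf <- function(x, y) rep(zc, length(x)) }

  px <- px_size_um
  nx <- round(geom$domain[1] / px); ny <- round(geom$domain[2] / px)
  nt <- length(truth$times)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  zmat <- outer(ys, xs, function(yy, xx) sf(xx, yy))
  if (any(zmat < 0) || any(zmat > (n_slices - 1) * z_step_um))
    stop("surface height field leaves the z range of the stack")
  gx <- abs(zmat[, -1] - zmat[, -nx]) / px
  gy <- abs(zmat[-1, ] - zmat[-ny, ]) / px
  if (max(gx, gy) > 1 + 1e-6)
    stop("surface height field too steep (|grad z| must be <= 1 um/um)")
  kmat <- round(zmat / z_step_um) + 1L     # shell slice per pixel

  set.seed(seed)
  arr <- array(0, dim = c(nt, n_slices, 2, ny, nx),
               dimnames = list(NULL, NULL, c("membrane", "myosin"), NULL, NULL))
  labs <- array(0L, dim = c(nt, ny, nx))
  surf <- array(rep(zmat, each = nt), dim = c(nt, ny, nx))
  band_px <- optics$band_width_um / px
  myo <- matrix(truth$truth$myosin_true, nrow = nt)   # frames x cells

  for (tix in seq_len(nt)) {
    polys <- epithelium_polygons(geom, truth$vertices[[tix]])
    lab <- rasterize_cells(polys, geom$domain, px)
    bnd <- label_boundaries(lab)
    lab[bnd] <- 0L
    labs[tix, , ] <- lab
    dist <- EBImage::distmap(t(lab > 0))            # distance to skeleton, px
    dist <- t(as.matrix(dist))
    memb <- matrix(0, ny, nx)
    memb[bnd] <- optics$membrane_intensity
    myoim <- matrix(0, ny, nx)
    medial <- lab > 0 & dist > band_px
    myoim[medial] <- myo[tix, lab[medial]]
    myoim[bnd] <- optics$junctional_intensity
    for (ch in 1:2) {
      im <- if (ch == 1) memb else myoim
      for (k in unique(as.vector(kmat))) {
        sl <- matrix(0, ny, nx)
        sel <- kmat == k
        sl[sel] <- im[sel]
        arr[tix, k, ch, , ] <- arr[tix, k, ch, , ] + sl
      }
    }
  }

  if (optics$psf_sigma > 0) {
    sp <- optics$psf_sigma / px
    sz <- optics$psf_sigma / z_step_um
    kz <- stats::dnorm(-2:2, sd = max(sz, 1e-6)); kz <- kz / sum(kz)
    for (tix in seq_len(nt)) for (ch in 1:2) {
      stack <- arr[tix, , ch, , ]
      for (k in seq_len(n_slices))
        stack[k, , ] <- gauss_blur(stack[k, , ], sp)
      if (sz > 0.05) {
        out <- array(0, dim(stack))
        for (dz in -2:2) {
          ks <- pmin(pmax(seq_len(n_slices) + dz, 1), n_slices)
          out <- out + kz[dz + 3] * stack[ks, , ]
        }
        stack <- out
      }
      arr[tix, , ch, , ] <- stack
    }
  }

  arr <- arr + optics$background
  if (optics$photon_noise_scale > 0) {
    s <- optics$photon_noise_scale
    n <- length(arr)
    arr[] <- stats::rpois(n, arr / s) * s +
      stats::rnorm(n, 0, optics$read_noise_sd)
    arr[arr < 0] <- 0
  }

  structure(list(intensities = arr, channels = c("membrane", "myosin"),
                 px_size_um = px, z_step_um = z_step_um,
                 frame_interval_s = if (nt > 1) diff(truth$times[1:2]) else NA_real_,
                 surface_truth = surf, labels_truth = labs, truth = truth,
                 optics = optics, seed = seed),
            class = "synthetic_movie")
}

#' @export
print.synthetic_movie <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("synthetic_movie: %d frames x %d slices x 2 ch x %dx%d px (%.2f um/px, %.0f um z-step)\n",
              d[1], d[2], d[4], d[5], x$px_size_um, x$z_step_um))
  invisible(x)
}

#' Render a single fixed-placode image (one frame, one surface)
#'
#' Wraps [make_fixed_placode()] geometry into a 1-frame `synthetic_movie` plus
#' its truth table, for the area/dispersion analyses of fixed tissue.
#'
#' @inheritParams make_fixed_placode
#' @param optics a `render_optics`
#' @return list with `movie` (1-frame `synthetic_movie`-like object), `truth`,
#'   `geom`
#' @export
render_fixed_placode <- function(pattern = c("wildtype_gradient", "dispersed"),
                                 n_cells = 150, seed = 1L,
                                 optics = render_optics()) {
  fx <- make_fixed_placode(pattern, n_cells, seed)
  # wrap as a 1-frame dynamics truth
  polys <- epithelium_polygons(fx$geom)
  areas <- vapply(polys, poly_area, 0)
  dyn <- structure(list(
    truth = data.frame(cell_id = seq_along(polys), frame = 1L, t_s = 0,
                       area_um2 = areas, radius_um = sqrt(areas / pi),
                       myosin_true = 10, phase_true = 0,
                       placode_flag = fx$geom$placode_mask),
    vertices = list(fx$geom$vertices), geom = fx$geom,
    params = oscillation_params(), times = 0, seed = seed),
    class = "dynamics_truth")
  mov <- render_movie(dyn, optics, seed = seed)
  list(movie = mov, truth = fx$truth, geom = fx$geom, pattern = fx$pattern)
}
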