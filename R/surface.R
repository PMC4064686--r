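#' Fit the apical "blanket" surface over the cortical signal in a z-stack
#'
#' For each lateral position the surface height is placed where the
#' (Gaussian-smoothed) cortical signal is strongest, subject to a Lipschitz
#' smoothness bound: the height difference between 4-neighbor pixels may not
#' exceed `smoothness_bound` um per um. The bound is enforced by min-plus
#' erosion (the largest bound-Lipschitz surface nowhere above the per-column
#' optimum), after a 3x3 median filter suppresses isolated column outliers.
#' A bound of 0 forces a flat plane at the globally best slice.
#'
#' @param zstack 3D array (z, y, x) of intensities
#' @param px_size_um lateral pixel size, um
#' @param z_step_um axial slice spacing, um
#' @param smoothness_bound maximum |grad height|, um/um (default 1)
#' @param smooth_sigma_um lateral Gaussian smoothing of each slice before
#'   scoring, um
#' @return a `surface_map`: list with `height` (y, x matrix, um; slice k
#'   corresponds to height (k-1)*z_step_um), `smoothness_bound`, `z_step_um`,
#'   `px_size_um`
#' @export
fit_blanket <- function(zstack, px_size_um, z_step_um = 1,
                        smoothness_bound = 1, smooth_sigma_um = 0.8) {
  stopifnot(length(dim(zstack)) == 3, dim(zstack)[1] >= 3,
            smoothness_bound >= 0)
  if (all(zstack == 0)) stop("no cortical signal")
  nz <- dim(zstack)[1]; ny <- dim(zstack)[2]; nx <- dim(zstack)[3]
  score <- zstack
  sp <- smooth_sigma_um / px_size_um
  if (sp > 0) {
    for (k in seq_len(nz)) score[k, , ] <- EBImage::gblur(score[k, , ], sp)
  }
  if (smoothness_bound == 0) {
    tot <- apply(score, 1, sum)
    k <- which.max(tot)
    h <- matrix((k - 1) * z_step_um, ny, nx)
    return(structure(list(height = h, smoothness_bound = 0,
                          z_step_um = z_step_um, px_size_um = px_size_um),
                     class = "surface_map"))
  }
  kbest <- apply(score, c(2, 3), which.max)
  h <- (kbest - 1) * z_step_um
  h <- median3x3(h)
  # Lipschitz projection: largest surface <= h with |grad| <= bound.
  step <- smoothness_bound * px_size_um
  repeat {
    h2 <- h
    h2[-1, ]  <- pmin(h2[-1, ],  h[-ny, ] + step)
    h2[-ny, ] <- pmin(h2[-ny, ], h[-1, ]  + step)
    h2[, -1]  <- pmin(h2[, -1],  h[, -nx] + step)
    h2[, -nx] <- pmin(h2[, -nx], h[, -1]  + step)
    if (max(abs(h2 - h)) < 1e-9) break
    h <- h2
  }
  structure(list(height = h, smoothness_bound = smoothness_bound,
                 z_step_um = z_step_um, px_size_um = px_size_um),
            class = "surface_map")
}

# 3x3 median filter with edge replication.
median3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- m[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  sh <- lapply(list(c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 1), c(1, 2),
                    c(2, 0), c(2, 1), c(2, 2)),
               function(o) pad[o[1] + seq_len(ny), o[2] + seq_len(nx)])
  stk <- array(unlist(sh), dim = c(ny, nx, 9))
  apply(stk, c(1, 2), stats::median)
}

#' Maximum-intensity projection of a thin layer below the blanket surface
#'
#' For each lateral position, takes the maximum intensity over slices between
#' the surface height and `thickness_um` below it (inclusive endpoints after
#' rounding to the nearer slice; no sub-slice interpolation). Slices outside
#' the stack are clamped with a warning.
#'
#' @param zstack 3D array (z, y, x)
#' @param surface a `surface_map` with matching lateral shape
#' @param thickness_um layer thickness, um (> 0); 1 um at 1 um z-step spans
#'   exactly two slices
#' @return 2D matrix (y, x) of projected intensities
#' @export
project_layer <- function(zstack, surface, thickness_um = 1) {
  stopifnot(thickness_um > 0, inherits(surface, "surface_map"))
  nz <- dim(zstack)[1]; ny <- dim(zstack)[2]; nx <- dim(zstack)[3]
  stopifnot(all(dim(surface$height) == c(ny, nx)))
  k0 <- round(surface$height / surface$z_step_um) + 1L
  k1 <- round((surface$height + thickness_um) / surface$z_step_um) + 1L
  if (any(k0 < 1) || any(k1 > nz)) {
    warning("projection slab clamped to stack depth at some pixels")
    k0 <- pmin(pmax(k0, 1L), nz); k1 <- pmin(pmax(k1, 1L), nz)
  }
  out <- matrix(-Inf, ny, nx)
  for (k in seq_len(nz)) {
    sel <- k >= k0 & k <= k1
    if (any(sel)) {
      sl <- zstack[k, , ]
      out[sel] <- pmax(out[sel], sl[sel])
    }
  }
  out
}

#' Extract projected two-channel frames from a movie's z-stacks
#'
#' Runs [fit_blanket()] on the membrane channel of every frame and projects
#' both channels through the fitted surface. Logs the median frame-to-frame
#' surface displacement as an attribute (each frame is fitted independently).
#'
#' @param movie a `synthetic_movie` (or compatible list with `intensities`
#'   (t,z,c,y,x), `px_size_um`, `z_step_um`)
#' @param thickness_um projection slab thickness, um (1 or 1.5 are typical)
#' @param smoothness_bound blanket smoothness bound, um/um
#' @return list of class `projected_frames`: `membrane` and `myosin` (lists of
#'   y-x matrices), `surfaces` (list of `surface_map`), `px_size_um`,
#'   `frame_interval_s`
#' @export
project_movie <- function(movie, thickness_um = 1, smoothness_bound = 1) {
  d <- dim(movie$intensities)
  nt <- d[1]
  memb <- vector("list", nt); myos <- vector("list", nt)
  surfs <- vector("list", nt)
  for (tix in seq_len(nt)) {
    stk_m <- movie$intensities[tix, , 1, , ]
    stk_y <- movie$intensities[tix, , 2, , ]
    sm <- fit_blanket(stk_m, movie$px_size_um, movie$z_step_um,
                      smoothness_bound)
    memb[[tix]] <- project_layer(stk_m, sm, thickness_um)
    myos[[tix]] <- project_layer(stk_y, sm, thickness_um)
    surfs[[tix]] <- sm
  }
  disp <- if (nt > 1) {
    stats::median(vapply(seq_len(nt - 1), function(i)
      stats::median(abs(surfs[[i + 1]]$height - surfs[[i]]$height)), 0))
  } else 0
  structure(list(membrane = memb, myosin = myos, surfaces = surfs,
                 px_size_um = movie$px_size_um,
                 frame_interval_s = movie$frame_interval_s,
                 thickness_um = thickness_um,
                 median_frame_displacement_um = disp),
            class = "projected_frames")
}
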