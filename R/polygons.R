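#' Signed polygon area (shoelace formula)
#'
#' @param poly numeric matrix, n x 2, vertices in order (open ring; the closing
#'   edge is implicit). Units are preserved (typically um).
#' @return signed area; positive for counter-clockwise orientation.
#' @keywords internal
poly_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Polygon area (absolute, shoelace)
#' @inheritParams poly_area_signed
#' @return area >= 0
#' @export
poly_area <- function(poly) abs(poly_area_signed(poly))

#' Polygon centroid (area-weighted)
#' @inheritParams poly_area_signed
#' @return length-2 numeric (x, y)
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

#' Test whether points fall inside a polygon (ray casting)
#'
#' Boundary points are resolved by the even-odd rule; for the pixel-center
#' rasterization used here that ambiguity affects at most a zero-measure set.
#'
#' @param px,py coordinates of query points (vectors)
#' @param poly n x 2 vertex matrix
#' @return logical vector
#' @export
points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Clip polygon by half-plane {p : a.p <= b} (Sutherland-Hodgman, one edge).
clip_halfplane <- function(poly, a, b) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  d <- as.vector(poly %*% a) - b
  n <- nrow(poly)
  keep_x <- numeric(0); keep_y <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    di <- d[i]; dj <- d[j]
    if (dj <= 0 && di <= 0) {            # both inside
      keep_x <- c(keep_x, poly[i, 1]); keep_y <- c(keep_y, poly[i, 2])
    } else if (dj <= 0 && di > 0) {      # leaving: add intersection
      t <- dj / (dj - di)
      keep_x <- c(keep_x, poly[j, 1] + t * (poly[i, 1] - poly[j, 1]))
      keep_y <- c(keep_y, poly[j, 2] + t * (poly[i, 2] - poly[j, 2]))
    } else if (dj > 0 && di <= 0) {      # entering: intersection then vertex
      t <- dj / (dj - di)
      keep_x <- c(keep_x, poly[j, 1] + t * (poly[i, 1] - poly[j, 1]), poly[i, 1])
      keep_y <- c(keep_y, poly[j, 2] + t * (poly[i, 2] - poly[j, 2]), poly[i, 2])
    }
    j <- i
  }
  if (length(keep_x) < 3) return(NULL)
  cbind(x = keep_x, y = keep_y)
}

# Remove consecutive duplicate vertices (within tol).
dedup_poly <- function(poly, tol = 1e-9) {
  if (is.null(poly)) return(NULL)
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  keep <- sqrt((poly[, 1] - poly[i2, 1])^2 + (poly[, 2] - poly[i2, 2])^2) > tol
  keep <- c(keep[n], keep[-n])  # drop vertex identical to its predecessor
  out <- poly[keep, , drop = FALSE]
  if (nrow(out) < 3) NULL else out
}

#' Check that a polygon is simple (no self-intersections)
#' @inheritParams poly_area_signed
#' @return logical scalar
#' @export
poly_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      s1 <- seg(i); s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(FALSE)
    }
  }
  TRUE
}

#' Inward offset of a convex (or near-convex) polygon
#'
#' Each edge is translated inward by `band` and the polygon is re-clipped by
#' the shifted half-planes; for convex polygons this is the exact inner
#' parallel body. Returns NULL when the offset empties the polygon.
#'
#' @param poly n x 2 vertex matrix
#' @param band offset distance (same units as vertices), >= 0
#' @export
poly_inward_offset <- function(poly, band) {
  stopifnot(band >= 0)
  if (band == 0) return(poly)
  if (poly_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  out <- poly
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  for (i in seq_len(n)) {
    e <- poly[i2[i], ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(e[2], -e[1]) / len            # outward normal for CCW ring
    b <- sum(nrm * poly[i, ]) - band
    out <- clip_halfplane(out, nrm, b)
    if (is.null(out)) return(NULL)
  }
  dedup_poly(out)
}
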