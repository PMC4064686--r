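#' Generate a synthetic epithelial cell field
#'
#' Builds a conforming polygonal tiling of a rectangular domain as the Voronoi
#' tessellation of a jittered hexagonal lattice, the standard idealization of
#' an epithelial apical surface. Cells inside a configurable ellipse around the
#' invagination-pit center are flagged as placodal; the remaining margin cells
#' play the role of surrounding epidermis.
#'
#' @param n_cells number of cells (>= 1)
#' @param domain c(width, height) of the field in um
#' @param jitter site displacement as a fraction of the lattice pitch, in
#'   [0, 0.5]; 0 gives regular hexagons for interior cells
#' @param seed integer RNG seed; output is a pure function of the arguments
#' @param pit_center pit position in um; default places the pit off-center,
#'   mimicking the dorsal-posterior invagination corner
#' @param placode_ellipse semi-axes (um) of the placode ellipse centered on
#'   the domain center; cells whose site falls inside are placodal
#' @return an `epithelium` object: list with `vertices` (m x 2 um), `cells`
#'   (list of vertex-index rings, CCW), `sites`, `adjacency` (2-column matrix
#'   of cell-id pairs sharing an edge), `pit_center`, `domain`,
#'   `placode_mask` (logical per cell).
#' @export
generate_epithelium <- function(n_cells, domain = c(80, 80), jitter = 0.25,
                                seed = 1L,
                                pit_center = NULL,
                                placode_ellipse = 0.48 * domain) {
  stopifnot(n_cells >= 1, jitter >= 0, jitter <= 0.5)
  if (any(domain <= 0)) stop("domain must have positive width and height")
  w <- domain[1]; h <- domain[2]
  pitch <- sqrt(2 * w * h / (sqrt(3) * n_cells))
  if (pitch < 1) stop("n_cells exceeds what the domain can hold at >= 1 um pitch")
  if (is.null(pit_center)) pit_center <- c(0.62 * w, 0.38 * h)

  set.seed(seed)
  if (n_cells == 1) {
    verts <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
    return(structure(list(
      vertices = verts, cells = list(1:4), sites = rbind(c(w, h) / 2),
      adjacency = matrix(integer(0), ncol = 2),
      pit_center = pit_center, domain = domain,
      placode_mask = TRUE), class = "epithelium"))
  }

  # Hex lattice, jittered; keep sites inside the domain (their Voronoi cells
  # partition the rectangle with no boundary slivers), densifying if needed.
  make_sites <- function(pitch) {
    dy <- pitch * sqrt(3) / 2
    rows <- seq(dy / 2, h - dy / 4, by = dy)
    s <- do.call(rbind, lapply(seq_along(rows), function(r) {
      off <- if (r %% 2 == 0) pitch / 2 else pitch / 4
      xs <- seq(off, w - 1e-9, by = pitch)
      cbind(xs, rows[r])
    }))
    s <- s + matrix(stats::runif(length(s), -jitter, jitter) * pitch, ncol = 2)
    s[s[, 1] > 0 & s[, 1] < w & s[, 2] > 0 & s[, 2] < h, , drop = FALSE]
  }
  p_try <- pitch
  sites <- make_sites(p_try)
  while (nrow(sites) < n_cells) {
    p_try <- p_try * 0.95
    sites <- make_sites(p_try)
  }
  ctr <- c(w, h) / 2
  d2ctr <- (sites[, 1] - ctr[1])^2 + (sites[, 2] - ctr[2])^2
  cand <- order(d2ctr)
  if (length(cand) < n_cells) stop("lattice underfills the domain")

  rect <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
  voronoi_cells <- function(sel) {
    s <- sites[sel, , drop = FALSE]
    lapply(seq_len(nrow(s)), function(i) {
      p <- rect
      si <- s[i, ]
      d2 <- (s[, 1] - si[1])^2 + (s[, 2] - si[2])^2
      for (j in order(d2)[-1]) {
        a <- s[j, ] - si
        b <- sum(a * (si + s[j, ]) / 2)
        p <- clip_halfplane(p, a, b)
        if (is.null(p)) return(NULL)
      }
      dedup_poly(p, tol = 1e-7)   # zero-width slivers count as empty
    })
  }
  # A selected site lying outside the rectangle can end up with an empty cell
  # against the selected subset; swap in the next-most-central candidates.
  sel <- cand[seq_len(n_cells)]
  next_i <- n_cells + 1L
  repeat {
    polys <- voronoi_cells(sel)
    empty <- vapply(polys, is.null, TRUE)
    if (!any(empty)) break
    need <- sum(empty)
    if (next_i + need - 1L > length(cand)) stop("could not place all cells in domain")
    sel <- c(sel[!empty], cand[next_i:(next_i + need - 1L)])
    next_i <- next_i + need
  }
  sites <- sites[sel, , drop = FALSE]
  polys <- lapply(polys, function(p) {
    if (poly_area_signed(p) < 0) p <- p[rev(seq_len(nrow(p))), ]
    p
  })

  # Weld shared vertices across cells so the tiling is a true mesh.
  key <- function(v) paste(round(v[, 1], 6), round(v[, 2], 6))
  all_keys <- unlist(lapply(polys, key))
  uk <- unique(all_keys)
  vid <- stats::setNames(seq_along(uk), uk)
  verts <- matrix(0, length(uk), 2)
  cells <- vector("list", n_cells)
  pos <- 1L
  for (i in seq_len(n_cells)) {
    k <- key(polys[[i]])
    ids <- vid[k]
    verts[ids, ] <- polys[[i]]
    cells[[i]] <- unname(ids)
    pos <- pos + length(ids)
  }

  # Edge-induced adjacency: two cells share an edge iff they share 2+ vertices.
  edge_of <- function(ring) {
    i2 <- c(ring[-1], ring[1])
    paste(pmin(ring, i2), pmax(ring, i2))
  }
  emap <- new.env(hash = TRUE)
  adj <- list()
  for (i in seq_len(n_cells)) {
    for (e in edge_of(cells[[i]])) {
      prev <- emap[[e]]
      if (is.null(prev)) emap[[e]] <- i
      else adj[[length(adj) + 1L]] <- c(prev, i)
    }
  }
  adj <- if (length(adj)) do.call(rbind, adj) else matrix(integer(0), ncol = 2)

  ex <- (sites[, 1] - ctr[1]) / placode_ellipse[1]
  ey <- (sites[, 2] - ctr[2]) / placode_ellipse[2]
  placode <- ex^2 + ey^2 <= 1

  structure(list(vertices = verts, cells = cells, sites = sites,
                 adjacency = adj, pit_center = pit_center, domain = domain,
                 placode_mask = placode),
            class = "epithelium")
}

#' Extract cell polygons from an epithelium mesh
#' @param geom an `epithelium`
#' @param vertices optional replacement vertex matrix (same indexing)
#' @return list of n x 2 matrices (um)
#' @export
epithelium_polygons <- function(geom, vertices = NULL) {
  v <- if (is.null(vertices)) geom$vertices else vertices
  lapply(geom$cells, function(ids) v[ids, , drop = FALSE])
}

#' @export
print.epithelium <- function(x, ...) {
  cat(sprintf("epithelium: %d cells (%d placodal), domain %.0fx%.0f um, pit (%.1f, %.1f)\n",
              length(x$cells), sum(x$placode_mask), x$domain[1], x$domain[2],
              x$pit_center[1], x$pit_center[2]))
  invisible(x)
}

# Vertices lying on the domain boundary (used to pin the tiling during
# area realization). Returns per-vertex logical columns: on left/right/top/bottom.
boundary_flags <- function(geom, tol = 1e-6) {
  v <- geom$vertices
  cbind(l = abs(v[, 1]) < tol, r = abs(v[, 1] - geom$domain[1]) < tol,
        b = abs(v[, 2]) < tol, t = abs(v[, 2] - geom$domain[2]) < tol)
}

# Flattened ring indexing for vectorized mesh operations: one entry per
# (cell, ring position), with the vertex id, its successor in the ring, and
# the owning cell.
build_mesh_index <- function(geom) {
  rings <- geom$cells
  ids <- unlist(rings)
  list(ids = ids,
       cell_of = rep(seq_along(rings), lengths(rings)),
       nxt = unlist(lapply(rings, function(r) c(r[-1], r[1]))),
       vcount = as.vector(rowsum(rep(1, length(ids)), ids)))
}

# Realize per-cell target areas on the shared-vertex mesh. Each cell proposes
# scaling its ring about its centroid by sqrt(target/current); every vertex
# moves toward the mean of its cells' proposals, with (i) an annealed
# Laplacian smoothing term that keeps mesh quality early in the iteration and
# (ii) a per-vertex displacement cap tied to the local mean edge length, which
# prevents edge crossings (mesh folds). Boundary vertices stay pinned to their
# domain edge, so the tiling remains a conforming partition of the rectangle.
realize_areas <- function(geom, targets, n_iter = 30, damp = 0.8,
                          lambda0 = 0.15, vertices = NULL, mesh_index = NULL) {
  v <- if (is.null(vertices)) geom$vertices else vertices
  mi <- if (is.null(mesh_index)) build_mesh_index(geom) else mesh_index
  bf <- boundary_flags(geom)
  ids <- mi$ids; nxt <- mi$nxt; cof <- mi$cell_of
  both <- c(ids, nxt)
  ndeg <- as.vector(rowsum(rep(1, length(both)), both))
  for (it in seq_len(n_iter)) {
    x <- v[, 1]; y <- v[, 2]
    cr <- x[ids] * y[nxt] - x[nxt] * y[ids]
    A2 <- as.vector(rowsum(cr, cof))                     # 2 * signed area
    A <- abs(A2) / 2
    cx <- as.vector(rowsum((x[ids] + x[nxt]) * cr, cof)) / (3 * A2)
    cy <- as.vector(rowsum((y[ids] + y[nxt]) * cr, cof)) / (3 * A2)
    s <- 1 + damp * (sqrt(targets / A) - 1)
    s <- pmin(pmax(s, 0.9), 1.1)
    px <- cx[cof] + s[cof] * (x[ids] - cx[cof])
    py <- cy[cof] + s[cof] * (y[ids] - cy[cof])
    nx <- as.vector(rowsum(px, ids)) / mi$vcount
    ny <- as.vector(rowsum(py, ids)) / mi$vcount
    lam <- lambda0 * max(0, 1 - it / (0.6 * n_iter))
    if (lam > 0) {
      nbx <- as.vector(rowsum(c(x[nxt], x[ids]), both))
      nby <- as.vector(rowsum(c(y[nxt], y[ids]), both))
      nx <- nx + lam * (nbx / ndeg - x)
      ny <- ny + lam * (nby / ndeg - y)
    }
    el <- sqrt((x[ids] - x[nxt])^2 + (y[ids] - y[nxt])^2)
    medge <- as.vector(rowsum(c(el, el), both)) / ndeg
    dxv <- nx - x; dyv <- ny - y
    dn <- sqrt(dxv^2 + dyv^2)
    f <- pmin(1, pmin(0.18 * medge, 0.3) / pmax(dn, 1e-12))
    x <- x + dxv * f; y <- y + dyv * f
    x[bf[, "l"]] <- 0; x[bf[, "r"]] <- geom$domain[1]
    y[bf[, "b"]] <- 0; y[bf[, "t"]] <- geom$domain[2]
    v <- cbind(pmin(pmax(x, 0), geom$domain[1]),
               pmin(pmax(y, 0), geom$domain[2]))
  }
  v
}
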