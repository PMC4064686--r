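#' Segment cell apices in a projected membrane image
#'
#' Adaptive watershed: the membrane image is Gaussian-smoothed, locally
#' contrast-normalized over blocks (subtract the block-local mean, divide by
#' the block-local standard deviation, which makes the segmentation invariant
#' to multiplying the image by a positive constant), and inverted so cell
#' interiors become ridges. Seeds are the regional maxima of the inverted
#' relief separated by at least `seed_min_distance_um`; basins are grown with
#' intensity-weighted propagation (one basin per seed) and pixels where two
#' basins meet are labeled 0, so the skeleton separates 4-connected regions.
#'
#' @param membrane 2D matrix (y, x), the projected membrane channel
#' @param px_size_um pixel size, um
#' @param membrane_smoothing_um Gaussian pre-smoothing sigma, um
#' @param seed_min_distance_um minimum seed separation, um
#' @param adaptive_block_um block size of the local normalization, um
#' @param merge_evidence minimum membrane evidence (in local standard
#'   deviations above the local mean) a basin boundary must show; adjacent
#'   basins below it are merged, so featureless regions are not split by
#'   spurious seeds
#' @return integer label matrix (y, x); 0 = membrane skeleton / background
#' @export
segment_cells <- function(membrane, px_size_um,
                          membrane_smoothing_um = 0.5,
                          seed_min_distance_um = 2.5,
                          adaptive_block_um = 15,
                          merge_evidence = 1) {
  if (stats::sd(membrane) == 0) stop("no gradients")
  px <- px_size_um
  img <- EBImage::gblur(membrane, max(membrane_smoothing_um / px, 0.3))
  mu <- box_mean(img, round(adaptive_block_um / px))
  sdv <- sqrt(pmax(box_mean(img^2, round(adaptive_block_um / px)) - mu^2, 0))
  eps <- 1e-6 * mean(abs(img))
  norm <- (img - mu) / (sdv + eps)             # membrane high, interiors low
  relief <- -norm
  # seeds: distance-transform maxima of the interior mask, separated by at
  # least seed_min_distance_um (plateaus collapse to one connected seed each);
  # signal-free flat regions count as interior
  interior <- relief > 0 | sdv <= eps
  dist <- t(as.matrix(EBImage::distmap(t(interior))))
  dist <- EBImage::gblur(dist, 1)
  r <- max(1, round(seed_min_distance_um / px / 2))
  dil <- dilate_max(dist, r)
  seeds_mask <- dist >= dil - 1e-9 & dist > 0.5
  seeds <- EBImage::bwlabel(t(seeds_mask))      # EBImage works in (x, y)
  shifted <- t(relief) - min(relief)
  lab <- EBImage::propagate(shifted, seeds, lambda = 1e-4)
  lab <- t(as.matrix(lab))
  storage.mode(lab) <- "integer"
  lab <- merge_weak_boundaries(lab, norm, merge_evidence)
  b <- label_boundaries(lab)
  lab[b] <- 0L
  lab
}

# Hierarchical basin merging: adjacent labels whose mutual boundary pixels
# show mean normalized membrane intensity below `thresh` are merged
# (union-find). Keeps watershed basins only where actual cortical signal
# separates them.
merge_weak_boundaries <- function(lab, norm, thresh) {
  n <- max(lab)
  if (n < 2) return(lab)
  pairs <- list(); vals <- list()
  collect <- function(a, b, va, vb) {
    s <- a != b
    if (!any(s)) return()
    p <- cbind(pmin(a[s], b[s]), pmax(a[s], b[s]))
    pairs[[length(pairs) + 1]] <<- rbind(p, p)
    vals[[length(vals) + 1]] <<- c(va[s], vb[s])
  }
  ny <- nrow(lab); nx <- ncol(lab)
  collect(lab[-ny, ], lab[-1, ], norm[-ny, ], norm[-1, ])
  collect(lab[, -nx], lab[, -1], norm[, -nx], norm[, -1])
  p <- do.call(rbind, pairs); v <- unlist(vals)
  if (is.null(p) || nrow(p) == 0) return(lab)
  key <- paste(p[, 1], p[, 2])
  ev <- tapply(v, key, mean)
  weak <- names(ev)[ev < thresh]
  if (!length(weak)) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (w in weak) {
    ab <- as.integer(strsplit(w, " ")[[1]])
    ra <- find(ab[1]); rb <- find(ab[2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 0L)
  newid <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  out
}

# Boxcar local mean with edge-replicated padding (via cumulative sums).
box_mean <- function(m, w) {
  w <- max(3L, as.integer(w)); if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  pad <- m[pmin(pmax(seq_len(ny + 2 * h) - h, 1), ny),
           pmin(pmax(seq_len(nx + 2 * h) - h, 1), nx)]
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- rbind(0, cbind(0, t(cs)))
  i1 <- seq_len(ny); i2 <- i1 + w; j1 <- seq_len(nx); j2 <- j1 + w
  (cs[i2, j2] - cs[i1, j2] - cs[i2, j1] + cs[i1, j1]) / (w * w)
}

# Grayscale dilation (moving maximum) with a (2r+1) square, separable.
dilate_max <- function(m, r) {
  run_max <- function(mm, r) {
    out <- mm
    for (d in seq_len(r)) {
      n <- nrow(mm)
      out[seq_len(n - d), ] <- pmax(out[seq_len(n - d), ],
                                    mm[seq_len(n - d) + d, ])
      out[seq_len(n - d) + d, ] <- pmax(out[seq_len(n - d) + d, ],
                                        mm[seq_len(n - d), ])
      mm <- out
    }
    out
  }
  t(run_max(t(run_max(m, r)), r))
}

#' Link labels between consecutive frames by mutual overlap
#'
#' Greedy maximal-overlap bipartite matching: a pair is linkable iff its
#' overlap covers at least `min_overlap` of the smaller region; candidate
#' pairs are taken in order of decreasing overlap area (ties broken by
#' smaller label id), each label used at most once. Unmatched labels start or
#' terminate tracks.
#'
#' @param labels_t,labels_t1 integer label matrices of the same shape
#' @param min_overlap mutual overlap fraction threshold (default 0.5)
#' @return data.frame with columns `from`, `to`
#' @export
link_frames <- function(labels_t, labels_t1, min_overlap = 0.5) {
  stopifnot(all(dim(labels_t) == dim(labels_t1)))
  sel <- labels_t > 0 & labels_t1 > 0
  if (!any(sel)) return(data.frame(from = integer(0), to = integer(0)))
  ov <- as.data.frame(table(from = labels_t[sel], to = labels_t1[sel]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, ]
  ov$from <- as.integer(ov$from); ov$to <- as.integer(ov$to)
  n_from <- tabulate(labels_t[labels_t > 0])
  n_to <- tabulate(labels_t1[labels_t1 > 0])
  ov$frac <- ov$Freq / pmin(n_from[ov$from], n_to[ov$to])
  ov <- ov[ov$frac >= min_overlap, ]
  ov <- ov[order(-ov$Freq, ov$from, ov$to), ]
  used_from <- logical(max(ov$from, 0)); used_to <- logical(max(ov$to, 0))
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (!used_from[ov$from[i]] && !used_to[ov$to[i]]) {
      keep[i] <- TRUE
      used_from[ov$from[i]] <- TRUE; used_to[ov$to[i]] <- TRUE
    }
  }
  out <- ov[keep, c("from", "to")]
  rownames(out) <- NULL
  out
}

# Cell adjacency from a label image: two labels are neighbors iff pixels at
# distance <= 3 carry both labels (the separating skeleton written by
# segment_cells is up to 2 px wide, one pixel on each side of the ridge).
derive_adjacency <- function(lab) {
  pairs <- list()
  for (d in 1:3) {
    a <- lab[seq_len(nrow(lab) - d), ]; b <- lab[seq_len(nrow(lab) - d) + d, ]
    s <- a > 0 & b > 0 & a != b
    pairs[[length(pairs) + 1]] <- cbind(a[s], b[s])
    a <- lab[, seq_len(ncol(lab) - d)]; b <- lab[, seq_len(ncol(lab) - d) + d]
    s <- a > 0 & b > 0 & a != b
    pairs[[length(pairs) + 1]] <- cbind(a[s], b[s])
  }
  p <- do.call(rbind, pairs)
  if (is.null(p) || nrow(p) == 0) return(matrix(integer(0), ncol = 2))
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  unique(p)
}

#' Segment and track cells through a projected movie
#'
#' Segments every frame with [segment_cells()], links consecutive frames with
#' [link_frames()], and assembles per-instance measurements. Identities are
#' never reused: a label that fails to link starts a new track.
#'
#' @param frames a `projected_frames` from [project_movie()]
#' @param ... parameters passed to [segment_cells()]
#' @return a `cell_tracks` object: list with `instances` (data.frame: cell_id,
#'   frame, t_s, centroid_x_um, centroid_y_um, area_um2, radius_um, label,
#'   edge_flag, valid_flag, placode_flag), `labels` (per-frame matrices with
#'   basin labels renumbered to track ids), `adjacency` (per-frame matrices of
#'   track-id pairs), `px_size_um`, `frame_interval_s`
#' @export
track_cells <- function(frames, ...) {
  stopifnot(inherits(frames, "projected_frames"))
  nt <- length(frames$membrane)
  px <- frames$px_size_um
  dt <- frames$frame_interval_s
  labs <- lapply(seq_len(nt), function(i)
    segment_cells(frames$membrane[[i]], px, ...))
  # global track ids
  next_id <- 0L
  idmaps <- vector("list", nt)
  idmaps[[1]] <- seq_len(max(labs[[1]]))
  next_id <- max(labs[[1]])
  if (nt > 1) for (tix in 2:nt) {
    lk <- link_frames(labs[[tix - 1]], labs[[tix]])
    m <- integer(max(labs[[tix]]))
    m[lk$to] <- idmaps[[tix - 1]][lk$from]
    new <- which(m == 0L)
    if (length(new)) {
      m[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    idmaps[[tix]] <- m
  }
  inst <- list(); adjs <- vector("list", nt)
  for (tix in seq_len(nt)) {
    lab <- labs[[tix]]
    glab <- lab
    glab[lab > 0] <- idmaps[[tix]][lab[lab > 0]]
    labs[[tix]] <- glab
    adj <- derive_adjacency(glab)
    adjs[[tix]] <- adj
    idx <- which(glab > 0)
    ids <- glab[idx]
    yy <- ((idx - 1) %% nrow(glab)) + 1
    xx <- ((idx - 1) %/% nrow(glab)) + 1
    npx <- tabulate(ids)
    present <- which(npx > 0)
    cy <- rowsum(yy, ids)[, 1] / npx[present]
    cx <- rowsum(xx, ids)[, 1] / npx[present]
    on_edge <- rowsum(as.numeric(yy <= 2 | yy >= nrow(glab) - 1 |
                                 xx <= 2 | xx >= ncol(glab) - 1), ids)[, 1] > 0
    inst[[tix]] <- data.frame(
      cell_id = present, frame = tix,
      t_s = (tix - 1) * if (is.na(dt)) 0 else dt,
      centroid_x_um = (cx - 0.5) * px, centroid_y_um = (cy - 0.5) * px,
      area_um2 = npx[present] * px^2,
      radius_um = sqrt(npx[present] * px^2 / pi),
      edge_flag = on_edge, valid_flag = TRUE, placode_flag = NA)
  }
  instances <- do.call(rbind, inst)
  instances <- instances[order(instances$cell_id, instances$frame), ]
  rownames(instances) <- NULL
  structure(list(instances = instances, labels = labs, adjacency = adjs,
                 px_size_um = px, frame_interval_s = dt),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("cell_tracks: %d instances, %d tracks, %d frames\n",
              nrow(x$instances), length(unique(x$instances$cell_id)),
              length(x$labels)))
  invisible(x)
}

#' Quality-control filtering of cell tracks
#'
#' Flags (never deletes) cell instances violating any rule: apical area
#' outside `[area_min, area_max]`, speed relative to the median velocity of
#' adjacent cells above `rel_speed_max`, relative area-change rate |d ln A/dt| above
#' `area_rate_max`, membership in a track shorter than `min_track_len`, or
#' (optionally) contact with the field-of-view border. Geometry is never
#' altered; only `valid_flag` is set.
#'
#' @param tracks a `cell_tracks`
#' @param area_min,area_max allowed apical area range, um^2
#' @param rel_speed_max maximum speed relative to neighbors, um/min
#' @param area_rate_max maximum |d ln A/dt|, 1/min
#' @param min_track_len minimum track length, frames
#' @param drop_edge flag instances touching the field-of-view border
#' @return the `cell_tracks` with `valid_flag` updated
#' @export
qc_filter <- function(tracks, area_min = 2, area_max = 150,
                      rel_speed_max = 5, area_rate_max = 3,
                      min_track_len = 6, drop_edge = TRUE) {
  if (area_min > area_max) stop("area_min must not exceed area_max")
  ins <- tracks$instances
  ins$valid_flag <- TRUE
  ins$valid_flag[ins$area_um2 < area_min | ins$area_um2 > area_max] <- FALSE
  len <- table(ins$cell_id)
  ins$valid_flag[ins$cell_id %in%
                   as.integer(names(len)[len < min_track_len])] <- FALSE
  if (drop_edge) ins$valid_flag[ins$edge_flag] <- FALSE
  dt_min <- tracks$frame_interval_s / 60
  if (!is.na(dt_min) && dt_min > 0 && length(tracks$labels) > 1) {
    o <- order(ins$cell_id, ins$frame)
    ins <- ins[o, ]
    same <- c(FALSE, diff(ins$cell_id) == 0 & diff(ins$frame) == 1)
    vx <- c(NA, diff(ins$centroid_x_um)); vx[!same] <- NA
    vy <- c(NA, diff(ins$centroid_y_um)); vy[!same] <- NA
    dlnA <- c(NA, diff(log(ins$area_um2))); dlnA[!same] <- NA
    ins$speed_um_min <- sqrt(vx^2 + vy^2) / dt_min
    ins$dlnA_min <- dlnA / dt_min
    ins$valid_flag[!is.na(ins$dlnA_min) &
                     abs(ins$dlnA_min) > area_rate_max] <- FALSE
    # relative speed: own velocity minus the mean velocity of adjacent cells
    key <- paste(ins$cell_id, ins$frame)
    vx_of <- stats::setNames(vx / dt_min, key)
    vy_of <- stats::setNames(vy / dt_min, key)
    for (tix in seq_along(tracks$labels)) {
      adj <- tracks$adjacency[[tix]]
      if (nrow(adj) == 0) next
      both <- rbind(adj, adj[, 2:1])
      # median over neighbors: robust to one aberrant (e.g. mis-tracked) cell
      mvx <- tapply(vx_of[paste(both[, 2], tix)], both[, 1],
                    stats::median, na.rm = TRUE)
      mvy <- tapply(vy_of[paste(both[, 2], tix)], both[, 1],
                    stats::median, na.rm = TRUE)
      sel <- ins$frame == tix & as.character(ins$cell_id) %in% names(mvx)
      if (!any(sel)) next
      id_chr <- as.character(ins$cell_id[sel])
      rvx <- vx_of[paste(ins$cell_id[sel], tix)] - mvx[id_chr]
      rvy <- vy_of[paste(ins$cell_id[sel], tix)] - mvy[id_chr]
      rs <- sqrt(rvx^2 + rvy^2)
      bad <- which(sel)[!is.na(rs) & rs > rel_speed_max]
      ins$valid_flag[bad] <- FALSE
    }
  }
  tracks$instances <- ins
  tracks
}

#' Flag placodal cells by a mask polygon
#'
#' @param tracks a `cell_tracks`
#' @param mask_poly polygon (um) delimiting the placode; instances whose
#'   centroid falls inside are flagged placodal
#' @return the `cell_tracks` with `placode_flag` set
#' @export
flag_placode <- function(tracks, mask_poly) {
  ins <- tracks$instances
  ins$placode_flag <- points_in_poly(ins$centroid_x_um, ins$centroid_y_um,
                                     mask_poly)
  tracks$instances <- ins
  tracks
}

#' Ellipse polygon helper (for placode masks)
#' @param center,semiaxes ellipse parameters, um
#' @param n number of polygon vertices
#' @return n x 2 matrix
#' @export
ellipse_polygon <- function(center, semiaxes, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + semiaxes[1] * cos(th), center[2] + semiaxes[2] * sin(th))
}

#' Polygon outline of one labeled cell
#'
#' Convex hull of the cell's pixel centers, in um. Cell apices in these
#' tissues are near-convex, so the hull is a faithful outline; areas and
#' centroids of tracked instances are computed from pixel counts, not from
#' this polygon.
#'
#' @param lab integer label matrix
#' @param id cell label
#' @param px_size_um pixel size, um
#' @return n x 2 matrix (um)
#' @export
label_polygon <- function(lab, id, px_size_um) {
  idx <- which(lab == id)
  if (!length(idx)) stop("label not present")
  yy <- ((idx - 1) %% nrow(lab) + 1 - 0.5) * px_size_um
  xx <- ((idx - 1) %/% nrow(lab) + 1 - 0.5) * px_size_um
  h <- grDevices::chull(xx, yy)
  cbind(xx[h], yy[h])[rev(seq_along(h)), , drop = FALSE]  # CCW
}
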