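#' Centerline curve
#'
#' An ordered 3-D polyline with cumulative arclength and unit tangents —
#' the backbone every measurement is taken along.
#'
#' @param points numeric matrix, n x 3, ordered positions in mm.
#' @param inscribed_radius optional numeric vector of maximal inscribed
#'   sphere radii (mm) per point.
#' @return object of class `centerline_curve` with fields `points`,
#'   `arclength` (cumulative mm, starting at 0), `tangents` (unit vectors)
#'   and optionally `inscribed_radius`.
#' @export
centerline_curve <- function(points, inscribed_radius = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 2L) {
    stop("points must be an n x 3 matrix with n >= 2")
  }
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    if (!is.null(inscribed_radius)) inscribed_radius <- inscribed_radius[keep]
    if (nrow(points) < 2L) stop("degenerate curve: all points coincide")
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  }
  s <- c(0, cumsum(seg))
  structure(list(points = points, arclength = s,
                 tangents = polyline_tangents(points),
                 inscribed_radius = inscribed_radius),
            class = "centerline_curve")
}

# Unit tangents by centered differences, one-sided at the endpoints.
polyline_tangents <- function(points) {
  n <- nrow(points)
  d <- matrix(0, n, 3)
  d[1, ] <- points[2, ] - points[1, ]
  d[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2L) {
    d[2:(n - 1), ] <- points[3:n, , drop = FALSE] -
      points[1:(n - 2), , drop = FALSE]
  }
  d / sqrt(rowSums(d^2))
}

#' Total arclength of a centerline (mm)
#' @param curve a `centerline_curve`.
#' @export
curve_length <- function(curve) {
  curve$arclength[length(curve$arclength)]
}

#' Point on a centerline at a given arclength
#' @param curve a `centerline_curve`.
#' @param s arclength in mm (vectorized), within `[0, curve_length(curve)]`.
#' @export
point_at <- function(curve, s) {
  L <- curve_length(curve)
  if (any(s < -1e-9 | s > L + 1e-9)) stop("arclength out of range [0, ", L, "]")
  s <- pmin(pmax(s, 0), L)
  cbind(stats::approx(curve$arclength, curve$points[, 1], xout = s)$y,
        stats::approx(curve$arclength, curve$points[, 2], xout = s)$y,
        stats::approx(curve$arclength, curve$points[, 3], xout = s)$y)
}

#' Unit tangent at a given arclength
#'
#' Tangents are centered finite differences at the curve samples,
#' interpolated linearly in between and re-normalized; one-sided at the
#' endpoints.
#' @param curve a `centerline_curve`.
#' @param s arclength in mm (vectorized).
#' @export
tangent_at <- function(curve, s) {
  L <- curve_length(curve)
  if (any(s < -1e-9 | s > L + 1e-9)) stop("arclength out of range [0, ", L, "]")
  s <- pmin(pmax(s, 0), L)
  t <- cbind(stats::approx(curve$arclength, curve$tangents[, 1], xout = s)$y,
             stats::approx(curve$arclength, curve$tangents[, 2], xout = s)$y,
             stats::approx(curve$arclength, curve$tangents[, 3], xout = s)$y)
  t / sqrt(rowSums(t^2))
}

#' Resample a centerline at uniform arclength spacing
#'
#' Endpoints are preserved; the actual spacing is the largest value not
#' exceeding `step_mm` that divides the curve length evenly.
#'
#' @param curve a `centerline_curve`.
#' @param step_mm requested spacing in mm; must be positive.
#' @export
resample_curve <- function(curve, step_mm) {
  if (!is.numeric(step_mm) || step_mm <= 0) stop("step_mm must be positive")
  L <- curve_length(curve)
  if (step_mm > L) stop("step_mm exceeds curve length")
  n <- as.integer(ceiling(L / step_mm - 1e-9)) + 1L
  s <- seq(0, L, length.out = n)
  r <- if (!is.null(curve$inscribed_radius)) {
    stats::approx(curve$arclength, curve$inscribed_radius, xout = s)$y
  }
  centerline_curve(point_at(curve, s), inscribed_radius = r)
}

# Moving-average smoothing of the interior points; endpoints are anchored.
smooth_polyline <- function(points, window = 5L) {
  n <- nrow(points)
  if (n <= 2L || window < 3L) return(points)
  half <- window %/% 2L
  sm <- points
  for (ax in 1:3) {
    x <- points[, ax]
    cs <- c(0, cumsum(x))
    i <- 2:(n - 1)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, n)
    sm[i, ax] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  sm
}

#' @export
print.centerline_curve <- function(x, ...) {
  cat(sprintf("centerline_curve: %d points, length %.3f mm\n",
              nrow(x$points), curve_length(x)))
  if (!is.null(x$inscribed_radius)) {
    cat(sprintf("  inscribed radius %.2f-%.2f mm\n",
                min(x$inscribed_radius), max(x$inscribed_radius)))
  }
  invisible(x)
}

#' Export a centerline as CSV (x, y, z, s, radius)
#' @param curve a `centerline_curve`.
#' @param path destination CSV file.
#' @export
write_centerline_csv <- function(curve, path) {
  df <- data.frame(x = curve$points[, 1], y = curve$points[, 2],
                   z = curve$points[, 3], s = curve$arclength,
                   radius = if (is.null(curve$inscribed_radius)) NA_real_
                            else curve$inscribed_radius)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract a lumen centerline from a voxel label map
#'
#' A minimum-cost path between two interior points on the 26-connected
#' voxel graph, with edge cost step-length / r^p where r is the distance
#' to the lumen boundary (Euclidean distance transform).  The exponent
#' pulls the path onto the ridge of maximal inscribed spheres; the path is
#' then smoothed with a moving average and resampled at uniform arclength.
#'
#' @param map a [voxel_map()]; every non-zero label is lumen.
#' @param source,target 3-D world points (mm) inside the lumen.
#' @param p exponent of the inscribed-radius weighting (default 2).
#' @param smooth_window moving-average window in path samples (default 5).
#' @param step_mm resampling step of the returned curve (default 0.5 mm).
#' @param snap_voxels endpoints falling just outside the labelled region
#'   (e.g. a cap center rasterized away) are snapped to the nearest
#'   interior voxel within this many voxels (default 2); the exact world
#'   points still become the curve endpoints.
#' @return a [centerline_curve()] with `inscribed_radius` populated from
#'   the distance transform.
#' @export
extract_centerline <- function(map, source, target, p = 2,
                               smooth_window = 5L, step_mm = 0.5,
                               snap_voxels = 2L) {
  stopifnot(inherits(map, "voxel_map"))
  inside <- map$array > 0L
  dims <- dim(inside)
  src_idx <- snap_inside(map, inside, source, snap_voxels)
  tgt_idx <- snap_inside(map, inside, target, snap_voxels)
  dt <- distance_transform(map)

  # compact ids for interior voxels
  # (snap_inside guarantees both endpoints are interior voxel indices)
  id <- array(0L, dims)
  nin <- sum(inside)
  id[inside] <- seq_len(nin)
  lin_in <- which(inside)
  coord <- arrayInd(lin_in, dims)

  # 13 positive offsets of the 26-neighborhood
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  dtv <- dt[lin_in]
  inv_r <- 1 / pmax(dtv, 1e-6)^p
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ok <- coord[, 1] + o[1] >= 1L & coord[, 1] + o[1] <= dims[1] &
          coord[, 2] + o[2] >= 1L & coord[, 2] + o[2] <= dims[2] &
          coord[, 3] + o[3] >= 1L & coord[, 3] + o[3] <= dims[3]
    nb_lin <- lin_in[ok] + o[1] + o[2] * dims[1] + o[3] * dims[1] * dims[2]
    nb_id <- id[nb_lin]
    both <- nb_id > 0L
    a <- id[lin_in[ok]][both]
    b <- nb_id[both]
    step_len <- sqrt(sum((o * map$spacing)^2))
    from <- c(from, a)
    to <- c(to, b)
    w <- c(w, step_len * 0.5 * (inv_r[a] + inv_r[b]))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  sid <- id[src_idx[1], src_idx[2], src_idx[3]]
  tid <- id[tgt_idx[1], tgt_idx[2], tgt_idx[3]]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = sid, to = tid, weights = w,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2L && sid != tid) {
    stop("no path: labeled region is disconnected between source and target")
  }
  pts <- index_to_world(map, coord[vp, , drop = FALSE])
  pts <- rbind(matrix(source, ncol = 3), pts, matrix(target, ncol = 3))
  # two smoothing passes with an intermediate resample: the first removes
  # voxel-level zigzag, the second the residual sub-voxel wiggle that
  # still inflates arclength when the lumen axis is oblique to the grid
  pts <- smooth_polyline(pts, window = smooth_window)
  curve <- resample_curve(centerline_curve(pts), step_mm)
  pts <- smooth_polyline(curve$points, window = smooth_window)
  curve <- resample_curve(centerline_curve(pts), step_mm)
  # inscribed radius from the distance transform at the resampled points
  ridx <- world_to_index(map, curve$points)
  ridx[, 1] <- pmin(pmax(ridx[, 1], 1L), dims[1])
  ridx[, 2] <- pmin(pmax(ridx[, 2], 1L), dims[2])
  ridx[, 3] <- pmin(pmax(ridx[, 3], 1L), dims[3])
  curve$inscribed_radius <- dt[cbind(ridx[, 1], ridx[, 2], ridx[, 3])]
  curve
}

# Map a world point to its voxel index, snapping to the nearest interior
# voxel within a small neighborhood when it rasterized just outside.
snap_inside <- function(map, inside, pt, snap_voxels) {
  dims <- dim(inside)
  idx <- world_to_index(map, pt)
  if (all(idx >= 1L) && all(idx <= dims) &&
      inside[idx[1], idx[2], idx[3]]) {
    return(idx)
  }
  r <- as.integer(snap_voxels)
  if (r > 0L) {
    best <- NULL
    bestd <- Inf
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      c2 <- idx + c(dx, dy, dz)
      if (any(c2 < 1L) || any(c2 > dims)) next
      if (!inside[c2[1], c2[2], c2[3]]) next
      w <- index_to_world(map, c2)
      d <- sum((w - pt)^2)
      if (d < bestd) { bestd <- d; best <- c2 }
    }
    if (!is.null(best)) return(best)
  }
  stop("source/target point lies outside the labeled region")
}

#' Locate the origin of a branch on its parent centerline
#'
#' Finds the point of closest approach of the branch's proximal end to the
#' parent curve.
#'
#' @param parent,branch `centerline_curve`s in the same coordinate frame;
#'   the branch's first point is its proximal end.
#' @param gate_mm maximum allowed closest-approach distance (default 10 mm)
#'   before a no-junction error is raised.
#' @return list with `s_parent` (arclength on the parent, mm) and
#'   `origin_point` (3-D).
#' @export
locate_branch_origin <- function(parent, branch, gate_mm = 10) {
  b0 <- branch$points[1, ]
  P <- parent$points
  n <- nrow(P)
  A <- P[-n, , drop = FALSE]
  B <- P[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  t <- rowSums(sweep(A, 2, b0, function(a, b) b - a) * AB) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  proj <- A + AB * t
  d2 <- rowSums(sweep(proj, 2, b0)^2)
  k <- which.min(d2)
  if (sqrt(d2[k]) > gate_mm) {
    stop(sprintf("no junction: branch start is %.1f mm from the parent (gate %g mm)",
                 sqrt(d2[k]), gate_mm))
  }
  seglen <- sqrt(len2[k])
  list(s_parent = parent$arclength[k] + t[k] * seglen,
       origin_point = proj[k, ])
}
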