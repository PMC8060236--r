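#' Slice a mesh with a plane and keep the loop around a seed point
#'
#' Intersects the triangle mesh with the plane and chains the crossing
#' segments into closed loops; among them the loop closest to
#' `seed_point` (normally the centerline point) is returned, ordered
#' counterclockwise about the plane normal.  Near a junction this picks
#' the lumen of interest rather than a sibling vessel's loop.
#'
#' @param mesh a [surface_mesh()].
#' @param plane_point point on the cutting plane (mm).
#' @param plane_normal plane normal (normalized internally).
#' @param seed_point 3-D point selecting among multiple loops; defaults to
#'   `plane_point`.
#' @param gate_mm maximum seed-to-loop distance before the section is
#'   rejected (default 25 mm).
#' @return object of class `closed_contour`: `plane_point`,
#'   `plane_normal`, `polygon` (n x 3, closed implicitly), `area` (mm^2).
#' @export
slice_mesh <- function(mesh, plane_point, plane_normal,
                       seed_point = plane_point, gate_mm = 25) {
  plane_normal <- plane_normal / sqrt(sum(plane_normal^2))
  loops <- plane_loops(mesh, plane_point, plane_normal)
  if (length(loops) == 0L) stop("open contour: plane does not cut the mesh in a closed loop")
  dmin <- vapply(loops, function(l) {
    min(sqrt(rowSums(sweep(l, 2, seed_point)^2)))
  }, numeric(1))
  k <- which.min(dmin)
  if (dmin[k] > gate_mm) {
    stop(sprintf("open contour: nearest loop is %.1f mm from the seed", dmin[k]))
  }
  poly <- loops[[k]]
  basis <- plane_basis(plane_normal)
  p2 <- project_to_plane(poly, plane_point, basis)
  a <- polygon_area(p2)
  if (a < 0) {
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
    p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
    a <- -a
  }
  structure(list(plane_point = plane_point, plane_normal = plane_normal,
                 polygon = poly, polygon2d = p2, area = a),
            class = "closed_contour")
}

plane_basis <- function(normal) {
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  rbind(u, v)
}

project_to_plane <- function(pts, plane_point, basis) {
  rel <- sweep(pts, 2, plane_point)
  cbind(rel %*% basis[1, ], rel %*% basis[2, ])
}

# Signed polygon area (positive = counterclockwise in the (u, v) basis).
polygon_area <- function(p2) {
  x <- p2[, 1]; y <- p2[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @export
print.closed_contour <- function(x, ...) {
  cat(sprintf("closed_contour: %d points, area %.3f mm^2\n",
              nrow(x$polygon), x$area))
  invisible(x)
}

#' Minimum and maximum Feret (caliper) diameters of a contour
#'
#' The maximum Feret diameter is the largest pairwise distance between
#' contour points; the minimum is the smallest width over all in-plane
#' directions.  Both are computed exactly on the convex hull by rotating
#' calipers, which is also well defined for non-convex kinked lumens.
#'
#' @param contour a `closed_contour` from [slice_mesh()], or an n x 2
#'   matrix of planar points.
#' @return named numeric vector `c(d_min = , d_max = )` in mm.
#' @export
feret_diameters <- function(contour) {
  p2 <- contour_points2d(contour)
  if (nrow(p2) < 3L) stop("contour needs at least 3 points")
  h <- grDevices::chull(p2)
  hp <- p2[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) stop("degenerate (collinear) contour")
  # max Feret: brute-force over hull vertices (hull is small)
  d2 <- as.matrix(stats::dist(hp))
  d_max <- max(d2)
  # min Feret: minimum width over hull edge directions
  nxt <- c(2:n, 1L)
  widths <- vapply(seq_len(n), function(i) {
    e <- hp[nxt[i], ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    pr <- hp %*% nrm
    max(pr) - min(pr)
  }, numeric(1))
  c(d_min = min(widths), d_max = d_max)
}

contour_points2d <- function(contour) {
  if (inherits(contour, "closed_contour")) return(contour$polygon2d)
  p <- as.matrix(contour)
  if (ncol(p) != 2L) stop("expected a closed_contour or an n x 2 matrix")
  p
}

#' Chord diameters through a reference point
#'
#' Alternative diameter definition for sensitivity analysis: the chord of
#' the contour through an interior reference point (the centerline
#' point), swept over directions; returns the min and max chord.
#'
#' @param contour a `closed_contour`.
#' @param ref_point 3-D reference point; defaults to the section's plane
#'   point.
#' @param n_dirs number of directions swept over 180 degrees.
#' @return named numeric vector `c(d_min = , d_max = )`.
#' @export
chord_diameters <- function(contour, ref_point = contour$plane_point,
                            n_dirs = 180L) {
  stopifnot(inherits(contour, "closed_contour"))
  basis <- plane_basis(contour$plane_normal)
  c0 <- as.vector(project_to_plane(matrix(ref_point, 1, 3),
                                   contour$plane_point, basis))
  p2 <- contour$polygon2d
  n <- nrow(p2)
  a <- p2
  b <- p2[c(2:n, 1L), , drop = FALSE]
  chords <- vapply(seq_len(n_dirs), function(k) {
    th <- (k - 1) * pi / n_dirs
    d <- c(cos(th), sin(th))
    nrm <- c(-d[2], d[1])
    fa <- (a[, 1] - c0[1]) * nrm[1] + (a[, 2] - c0[2]) * nrm[2]
    fb <- (b[, 1] - c0[1]) * nrm[1] + (b[, 2] - c0[2]) * nrm[2]
    cr <- (fa > 0) != (fb > 0)
    if (!any(cr)) return(NA_real_)
    t <- fa[cr] / (fa[cr] - fb[cr])
    px <- a[cr, 1] + t * (b[cr, 1] - a[cr, 1])
    py <- a[cr, 2] + t * (b[cr, 2] - a[cr, 2])
    pr <- (px - c0[1]) * d[1] + (py - c0[2]) * d[2]
    max(pr) - min(pr)
  }, numeric(1))
  chords <- chords[!is.na(chords)]
  if (length(chords) == 0L) stop("reference point outside the contour")
  c(d_min = min(chords), d_max = max(chords))
}

#' Shape index of a cross-section contour
#'
#' SI = minimum / maximum diameter, in (0, 1]; 1 is a perfectly circular
#' section, lower values flag eccentric or kinked lumens.
#'
#' @param contour a `closed_contour` (or n x 2 point matrix).
#' @param definition `"feret"` (default, caliper diameters) or `"chord"`
#'   (chords through the section's centerline point).
#' @export
shape_index <- function(contour, definition = c("feret", "chord")) {
  definition <- match.arg(definition)
  d <- if (definition == "feret") feret_diameters(contour)
       else chord_diameters(contour)
  unname(d["d_min"] / d["d_max"])
}

#' Shape-index profile along a centerline
#'
#' Generates cross-sections at uniform arclength spacing, perpendicular to
#' the centerline, and computes Feret diameters and shape index for each.
#' Sections within half a spacing of either endpoint are skipped (cap
#' artefacts), as are sections whose plane fails to produce a closed loop
#' near the centerline; if more than `max_fail_frac` of sections fail the
#' profile is rejected.
#'
#' @param mesh a [surface_mesh()] of the lumen.
#' @param curve the lumen [centerline_curve()].
#' @param spacing_mm distance between sections (default 1 mm).
#' @param definition diameter definition, see [shape_index()].
#' @param max_fail_frac maximum tolerated fraction of failed sections.
#' @param gate_mm seed gate passed to [slice_mesh()].
#' @return data.frame of class `si_profile` with columns `s`, `d_min`,
#'   `d_max`, `si`, `area`; attribute `n_failed` counts skipped sections,
#'   attribute `contours` keeps the section contours.
#' @export
si_profile <- function(mesh, curve, spacing_mm = 1,
                       definition = c("feret", "chord"),
                       max_fail_frac = 0.2, gate_mm = 25) {
  definition <- match.arg(definition)
  L <- curve_length(curve)
  ss <- seq(spacing_mm, L - spacing_mm / 2 + 1e-9, by = spacing_mm)
  ss <- ss[ss >= spacing_mm / 2 & ss <= L - spacing_mm / 2 + 1e-9]
  if (length(ss) == 0L) stop("curve too short for the requested spacing")
  rows <- vector("list", length(ss))
  contours <- vector("list", length(ss))
  n_failed <- 0L
  for (i in seq_along(ss)) {
    s <- ss[i]
    pt <- as.vector(point_at(curve, s))
    nrm <- as.vector(tangent_at(curve, s))
    sec <- try(slice_mesh(mesh, pt, nrm, seed_point = pt,
                          gate_mm = gate_mm), silent = TRUE)
    if (inherits(sec, "try-error")) {
      n_failed <- n_failed + 1L
      next
    }
    d <- if (definition == "feret") feret_diameters(sec)
         else chord_diameters(sec, ref_point = pt)
    rows[[i]] <- data.frame(s = s, d_min = d[["d_min"]],
                            d_max = d[["d_max"]],
                            si = d[["d_min"]] / d[["d_max"]],
                            area = sec$area)
    contours[[i]] <- sec
  }
  if (n_failed > max_fail_frac * length(ss)) {
    stop(sprintf("profile quality: %d of %d sections failed", n_failed,
                 length(ss)))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  attr(out, "contours") <- contours[!vapply(contours, is.null, logical(1))]
  class(out) <- c("si_profile", "data.frame")
  out
}

#' @export
print.si_profile <- function(x, ...) {
  cat(sprintf("si_profile: %d sections, s %.1f-%.1f mm, SI %.3f-%.3f (%d failed)\n",
              nrow(x), min(x$s), max(x$s), min(x$si), max(x$si),
              attr(x, "n_failed")))
  invisible(x)
}

#' Plot a shape-index profile along the centerline
#' @param x an `si_profile`.
#' @param ... passed to [plot()].
#' @export
plot.si_profile <- function(x, ...) {
  plot(x$s, x$si, type = "l", xlab = "arclength s (mm)",
       ylab = "shape index", ylim = c(min(0.5, min(x$si)), 1), ...)
  invisible(x)
}

#' Export an SI profile as CSV (s, d_min, d_max, si)
#' @param profile an `si_profile`.
#' @param path destination CSV.
#' @export
write_si_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("s", "d_min", "d_max", "si")],
                   path, row.names = FALSE)
  invisible(path)
}
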