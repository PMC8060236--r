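#' Specification of a tubular phantom
#'
#' Describes a tube by its generating centerline and per-arclength
#' profiles of mean radius, cross-section shape index (SI, the ratio of
#' minimum to maximum diameter of the elliptical section) and optional
#' in-plane twist.  Profiles may be constants, functions of normalized
#' arclength in `[0, 1]`, or two-column tables `(t, value)` interpolated
#' linearly.
#'
#' With mean radius r and SI e, the elliptical section has semi-axes
#' a = 2r/(1+e) and b = 2re/(1+e), so that (a+b)/2 = r and b/a = e.
#'
#' @param centerline numeric matrix of 3-D control points (mm); consecutive
#'   points must be distinct.  Treated as a dense polyline (use the
#'   [phantom_straight()], [phantom_arc()], [phantom_helix()] helpers to
#'   generate smooth curves).
#' @param radius mean radius profile (mm); constant, function or table.
#' @param si shape-index profile in (0, 1]; constant, function or table.
#' @param twist in-plane rotation of the elliptical section (degrees);
#'   constant, function or table.
#' @param sections_per_mm mesh resolution along the tube (default 2).
#' @param vertices_per_section mesh resolution around the tube (default 64).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(centerline, radius, si = 1, twist = 0,
                         sections_per_mm = 2, vertices_per_section = 64) {
  centerline <- as.matrix(centerline)
  storage.mode(centerline) <- "double"
  if (ncol(centerline) != 3L || nrow(centerline) < 2L) {
    stop("invalid spec: centerline needs >= 2 control points (3-D)")
  }
  seg <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                       centerline[-nrow(centerline), , drop = FALSE])^2))
  if (any(seg < 1e-12)) {
    stop("invalid spec: degenerate (repeated) consecutive control points")
  }
  rad_f <- as_profile(radius, "radius")
  si_f <- as_profile(si, "si")
  tw_f <- as_profile(twist, "twist")
  tt <- seq(0, 1, length.out = 257)
  if (any(rad_f(tt) <= 0)) stop("invalid spec: radius must be positive")
  ee <- si_f(tt)
  if (any(ee <= 0 | ee > 1 + 1e-12)) {
    stop("invalid spec: si (eccentricity) must lie in (0, 1]")
  }
  structure(list(centerline = centerline, radius = rad_f, si = si_f,
                 twist = tw_f, sections_per_mm = sections_per_mm,
                 vertices_per_section = as.integer(vertices_per_section)),
            class = "phantom_spec")
}

# Coerce a constant, function or (t, value) table to a function of
# normalized arclength.
as_profile <- function(x, what) {
  if (is.function(x)) return(function(t) as.numeric(x(t)))
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop(what, " table must have two columns (t, value)")
    force(x)
    return(function(t) stats::approx(x[, 1], x[, 2], xout = t,
                                     rule = 2)$y)
  }
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(t) rep(x, length(t)))
  }
  stop(what, " profile must be a constant, a function or a 2-column table")
}

#' Straight-tube phantom spec
#' @param length tube length (mm).
#' @param from start point, default origin; tube runs along +z.
#' @param direction unit axis direction, default c(0, 0, 1).
#' @param ... passed to [phantom_spec()] (radius, si, twist, resolution).
#' @export
phantom_straight <- function(length, from = c(0, 0, 0),
                             direction = c(0, 0, 1), ...) {
  direction <- direction / sqrt(sum(direction^2))
  n <- max(2L, ceiling(length * 4))
  t <- seq(0, length, length.out = n)
  phantom_spec(outer(t, direction) + rep(from, each = n), ...)
}

#' Circular-arc phantom spec
#'
#' A planar arc of given bend radius in the x-z plane, starting at the
#' origin heading along +z and bending toward +x.
#' @param bend_radius arc (bend) radius in mm.
#' @param angle_deg arc angle in degrees (90 = quarter circle).
#' @param ... passed to [phantom_spec()].
#' @export
phantom_arc <- function(bend_radius, angle_deg = 90, ...) {
  L <- bend_radius * angle_deg * pi / 180
  n <- max(8L, ceiling(L * 8))
  phi <- seq(0, angle_deg * pi / 180, length.out = n)
  pts <- cbind(bend_radius * (1 - cos(phi)), 0, bend_radius * sin(phi))
  phantom_spec(pts, ...)
}

#' Helical phantom spec
#' @param helix_radius radius of the helix (mm).
#' @param pitch axial advance per turn (mm).
#' @param turns number of turns.
#' @param ... passed to [phantom_spec()].
#' @export
phantom_helix <- function(helix_radius, pitch, turns = 1, ...) {
  L <- turns * sqrt((2 * pi * helix_radius)^2 + pitch^2)
  n <- max(16L, ceiling(L * 8))
  phi <- seq(0, turns * 2 * pi, length.out = n)
  pts <- cbind(helix_radius * cos(phi), helix_radius * sin(phi),
               pitch * phi / (2 * pi))
  phantom_spec(pts, ...)
}

#' Inject a localized kink (shape-index dip) into a phantom spec
#'
#' Lowers the SI profile by up to `si_drop` inside a window centred at
#' `at_arclength`, blended smoothly (raised-cosine) to zero at the window
#' edges — emulating the localized eccentric collapse ("kinking") seen in
#' under-supported stent segments.
#'
#' @param spec a [phantom_spec()].
#' @param at_arclength centre of the dip, mm along the tube.
#' @param si_drop depth of the dip (0 < si_drop < 1 leaves SI positive).
#' @param extent_mm full width of the affected window, mm.
#' @return a new `phantom_spec`.
#' @export
inject_kink <- function(spec, at_arclength, si_drop, extent_mm) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (si_drop < 0 || si_drop >= 1) stop("invalid spec: si_drop must be in [0, 1)")
  L <- polyline_len(spec$centerline)
  if (at_arclength - extent_mm / 2 < 0 || at_arclength + extent_mm / 2 > L) {
    stop("invalid spec: kink window extends outside the tube")
  }
  if (si_drop == 0) return(spec)
  base_si <- spec$si
  t0 <- at_arclength / L
  halfw <- (extent_mm / 2) / L
  new_si <- function(t) {
    w <- abs(t - t0) / halfw
    dip <- ifelse(w < 1, si_drop * 0.5 * (1 + cos(pi * w)), 0)
    base_si(t) - dip
  }
  if (any(new_si(seq(0, 1, length.out = 513)) <= 0)) {
    stop("invalid spec: kink drives SI to zero or below")
  }
  spec$si <- new_si
  spec
}

polyline_len <- function(points) {
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}

# Parallel-transport frame along a polyline: returns list(u, v) of unit
# normals per point, propagated without torsion (no Frenet frame flips).
parallel_transport_frame <- function(points, tangents) {
  n <- nrow(points)
  u <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- ref - sum(ref * t1) * t1
  u[1, ] <- u1 / sqrt(sum(u1^2))
  for (i in 2:n) {
    ta <- tangents[i - 1, ]
    tb <- tangents[i, ]
    ax <- c(ta[2] * tb[3] - ta[3] * tb[2],
            ta[3] * tb[1] - ta[1] * tb[3],
            ta[1] * tb[2] - ta[2] * tb[1])
    s <- sqrt(sum(ax^2))
    cth <- sum(ta * tb)
    if (s < 1e-12) {
      u[i, ] <- u[i - 1, ]
    } else {
      ax <- ax / s
      up <- u[i - 1, ]
      # Rodrigues rotation of the previous normal about ax by the
      # tangent turning angle
      u[i, ] <- up * cth + c(ax[2] * up[3] - ax[3] * up[2],
                             ax[3] * up[1] - ax[1] * up[3],
                             ax[1] * up[2] - ax[2] * up[1]) * s +
        ax * sum(ax * up) * (1 - cth)
    }
    # re-orthogonalize against accumulated numeric drift
    u[i, ] <- u[i, ] - sum(u[i, ] * tb) * tb
    u[i, ] <- u[i, ] / sqrt(sum(u[i, ]^2))
  }
  v <- cbind(tangents[, 2] * u[, 3] - tangents[, 3] * u[, 2],
             tangents[, 3] * u[, 1] - tangents[, 1] * u[, 3],
             tangents[, 1] * u[, 2] - tangents[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Build a watertight tube mesh from a phantom spec
#'
#' Sweeps an elliptical section along the generating curve using a
#' parallel-transport frame (stable on curved tubes, no frame flips at
#' inflections), caps both ends with triangle fans, and returns the mesh
#' together with the analytically known ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `mesh` (a [surface_mesh()]) and `truth` (a
#'   [phantom_truth()] holding the true centerline, length and SI profile).
#' @export
make_tube_mesh <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  curve <- resample_curve(centerline_curve(spec$centerline),
                          1 / spec$sections_per_mm)
  P <- curve$points
  n <- nrow(P)
  L <- curve_length(curve)
  tn <- curve$tangents
  fr <- parallel_transport_frame(P, tn)
  t_norm <- curve$arclength / L
  r <- spec$radius(t_norm)
  e <- spec$si(t_norm)
  a <- 2 * r / (1 + e)
  b <- 2 * r * e / (1 + e)
  tw <- spec$twist(t_norm) * pi / 180

  # self-intersection guard: the largest semi-axis must stay below the
  # local radius of curvature
  if (n > 2L) {
    kappa <- polyline_curvature(P, curve$arclength)
    bad <- which(a * kappa > 0.95)
    if (length(bad) > 0) {
      stop(sprintf(
        "geometry error: tube self-intersects near arclength %.1f mm (radius %.2f >= curvature radius %.2f)",
        curve$arclength[bad[1]], a[bad[1]], 1 / kappa[bad[1]]))
    }
  }

  k <- spec$vertices_per_section
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  verts <- matrix(0, n * k + 2L, 3)
  for (i in seq_len(n)) {
    uu <- cos(tw[i]) * fr$u[i, ] + sin(tw[i]) * fr$v[i, ]
    vv <- -sin(tw[i]) * fr$u[i, ] + cos(tw[i]) * fr$v[i, ]
    ring <- matrix(P[i, ], k, 3, byrow = TRUE) +
      outer(a[i] * cos(th), uu) + outer(b[i] * sin(th), vv)
    verts[((i - 1L) * k + 1L):(i * k), ] <- ring
  }
  # cap centers
  verts[n * k + 1L, ] <- P[1, ]
  verts[n * k + 2L, ] <- P[n, ]

  # side quads -> triangles, outward orientation
  i <- rep(seq_len(n - 1L), each = k)
  j <- rep(seq_len(k), n - 1L)
  jn <- j %% k + 1L
  v00 <- (i - 1L) * k + j
  v01 <- (i - 1L) * k + jn
  v10 <- i * k + j
  v11 <- i * k + jn
  faces <- rbind(cbind(v00, v01, v10), cbind(v01, v11, v10))
  # caps: fan at start (normal along -t), at end (+t)
  j <- seq_len(k)
  jn <- j %% k + 1L
  cap0 <- cbind(n * k + 1L, jn, j)
  cap1 <- cbind(n * k + 2L, (n - 1L) * k + j, (n - 1L) * k + jn)
  mesh <- surface_mesh(verts, rbind(faces, cap0, cap1), clean = FALSE)

  truth <- phantom_truth(
    centerline = curve,
    length = L,
    si_profile = data.frame(s = curve$arclength, si = e),
    radius_profile = data.frame(s = curve$arclength, radius = r))
  list(mesh = mesh, truth = truth)
}

# Discrete curvature magnitude |dT/ds| by centered differences.
polyline_curvature <- function(points, arclength) {
  tn <- polyline_tangents(points)
  n <- nrow(points)
  kappa <- numeric(n)
  if (n > 2L) {
    ds <- arclength[3:n] - arclength[1:(n - 2)]
    dT <- tn[3:n, , drop = FALSE] - tn[1:(n - 2), , drop = FALSE]
    kappa[2:(n - 1)] <- sqrt(rowSums(dT^2)) / ds
    kappa[1] <- kappa[2]
    kappa[n] <- kappa[n - 1]
  }
  kappa
}

#' Ground truth of a synthetic phantom
#'
#' The analytically known quantities of a generated phantom, used as the
#' oracle when validating the measurement pipeline.
#'
#' @param centerline true [centerline_curve()].
#' @param length true centerline length, mm.
#' @param si_profile data.frame (s, si) of the constructed shape index.
#' @param radius_profile data.frame (s, radius), mm.
#' @param takeoff_angle_deg constructed take-off angle (branches), degrees.
#' @param zone_lengths numeric length-3 vector (L1, L2, L3), mm.
#' @param landmarks list with `cuff_end_s` and `vessel_origin_s`, mm.
#' @param nominal_length nominal (labeled) stent length, mm.
#' @export
phantom_truth <- function(centerline, length, si_profile,
                          radius_profile = NULL, takeoff_angle_deg = NA_real_,
                          zone_lengths = NULL, landmarks = NULL,
                          nominal_length = NA_real_) {
  stopifnot(abs(curve_length(centerline) - length) < 1e-6 * max(length, 1))
  stopifnot(all(si_profile$si > 0 & si_profile$si <= 1 + 1e-12))
  structure(list(centerline = centerline, length = length,
                 si_profile = si_profile, radius_profile = radius_profile,
                 takeoff_angle_deg = takeoff_angle_deg,
                 zone_lengths = zone_lengths, landmarks = landmarks,
                 nominal_length = nominal_length),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: length %.3f mm, SI %.3f-%.3f\n", x$length,
              min(x$si_profile$si), max(x$si_profile$si)))
  if (!is.na(x$takeoff_angle_deg)) {
    cat(sprintf("  take-off angle %.1f deg\n", x$takeoff_angle_deg))
  }
  if (!is.null(x$zone_lengths)) {
    cat(sprintf("  zones %.1f / %.1f / %.1f mm\n", x$zone_lengths[1],
                x$zone_lengths[2], x$zone_lengths[3]))
  }
  invisible(x)
}

#' Specification of a bridging-stent branch on a parent vessel
#'
#' The branch leaves the parent at `origin_arclength` with the stated
#' take-off angle, measured against the cranially oriented parent tangent
#' (toward the parent's first point): 180 deg is a branch running straight
#' caudally, 0 deg recurves cranially.  Zone landmarks are arclengths
#' along the branch: zone 1 ends at `cuff_end_arclength` (end of the
#' main-body cuff), zone 2 ends at `vessel_origin_arclength` (origin of
#' the native target vessel), zone 3 runs to the stent end.
#'
#' @param origin_arclength mm along the parent centerline.
#' @param takeoff_angle_deg intended take-off angle in `[0, 180]`.
#' @param length branch length, mm (straight branch).
#' @param radius branch mean radius profile (mm).
#' @param si branch SI profile, default 1.
#' @param cuff_end_arclength zone-1/zone-2 boundary, mm along the branch.
#' @param vessel_origin_arclength zone-2/zone-3 boundary, mm.
#' @param nominal_stent_length labeled stent length, mm (defaults to the
#'   built length).
#' @param azimuth_deg rotation of the take-off plane about the parent
#'   tangent, degrees.
#' @param sections_per_mm,vertices_per_section mesh resolution.
#' @export
branch_spec <- function(origin_arclength, takeoff_angle_deg, length,
                        radius = 3, si = 1,
                        cuff_end_arclength = 0.25 * length,
                        vessel_origin_arclength = 0.7 * length,
                        nominal_stent_length = length,
                        azimuth_deg = 0,
                        sections_per_mm = 2, vertices_per_section = 64) {
  if (takeoff_angle_deg < 0 || takeoff_angle_deg > 180) {
    stop("invalid spec: takeoff_angle_deg must be in [0, 180]")
  }
  if (!(0 < cuff_end_arclength && cuff_end_arclength < vessel_origin_arclength &&
        vessel_origin_arclength < length)) {
    stop("invalid spec: need 0 < cuff_end < vessel_origin < branch length")
  }
  structure(list(origin_arclength = origin_arclength,
                 takeoff_angle_deg = takeoff_angle_deg,
                 length = length, radius = radius, si = si,
                 cuff_end_arclength = cuff_end_arclength,
                 vessel_origin_arclength = vessel_origin_arclength,
                 nominal_stent_length = nominal_stent_length,
                 azimuth_deg = azimuth_deg,
                 sections_per_mm = sections_per_mm,
                 vertices_per_section = as.integer(vertices_per_section)),
            class = "branch_spec")
}

#' Build a branched phantom (parent vessel plus bridging-stent branches)
#'
#' The parent tube and each branch tube are individually watertight closed
#' meshes merged into one labelled mesh (label 0 = parent, 1..n =
#' branches); [voxelize()] fills each component separately so the union is
#' handled without boolean surface operations.  Each branch starts on the
#' parent centerline, so its proximal portion lies inside the parent lumen
#' like a bridging stent inside its cuff.
#'
#' @param parent a [phantom_spec()] for the parent (aortic) lumen.
#' @param branches list of [branch_spec()]s.
#' @return list with `mesh` (labelled [surface_mesh()]), `parent_truth`,
#'   and `branch_truths` (list of [phantom_truth()], one per branch, with
#'   take-off angle, zone lengths and landmarks filled in).
#' @export
make_branched_phantom <- function(parent, branches) {
  stopifnot(inherits(parent, "phantom_spec"))
  if (inherits(branches, "branch_spec")) branches <- list(branches)
  pb <- make_tube_mesh(parent)
  pcurve <- pb$truth$centerline
  pL <- curve_length(pcurve)
  t_norm <- function(s) s / pL

  origins <- vapply(branches, `[[`, numeric(1), "origin_arclength")
  if (length(origins) > 1L) {
    pr <- parent$radius(t_norm(origins))
    d <- abs(outer(origins, origins, "-"))
    diag(d) <- Inf
    if (any(d < max(pr))) {
      stop("geometry error: branch origins closer than one parent radius")
    }
  }

  meshes <- list(pb$mesh)
  truths <- vector("list", length(branches))
  for (bi in seq_along(branches)) {
    bs <- branches[[bi]]
    if (bs$origin_arclength <= 0 || bs$origin_arclength >= pL) {
      stop("invalid spec: branch origin not on the parent curve")
    }
    P0 <- as.vector(point_at(pcurve, bs$origin_arclength))
    tpar <- as.vector(tangent_at(pcurve, bs$origin_arclength))
    cranial <- -tpar
    fr <- parallel_transport_frame(pcurve$points, pcurve$tangents)
    i0 <- which.min(abs(pcurve$arclength - bs$origin_arclength))
    az <- bs$azimuth_deg * pi / 180
    nrm <- cos(az) * fr$u[i0, ] + sin(az) * fr$v[i0, ]
    nrm <- nrm - sum(nrm * tpar) * tpar
    nrm <- nrm / sqrt(sum(nrm^2))
    th <- bs$takeoff_angle_deg * pi / 180
    dir <- cos(th) * cranial + sin(th) * nrm
    tb <- seq(0, bs$length, length.out = max(2L, ceiling(bs$length * 4)))
    bspec <- phantom_spec(
      sweep(outer(tb, dir), 2, P0, "+"),
      radius = bs$radius, si = bs$si,
      sections_per_mm = bs$sections_per_mm,
      vertices_per_section = bs$vertices_per_section)
    bb <- make_tube_mesh(bspec)
    meshes[[bi + 1L]] <- bb$mesh
    tr <- bb$truth
    tr$takeoff_angle_deg <- angle_between_deg(cranial, dir)
    tr$landmarks <- list(cuff_end_s = bs$cuff_end_arclength,
                         vessel_origin_s = bs$vessel_origin_arclength)
    tr$zone_lengths <- c(bs$cuff_end_arclength,
                         bs$vessel_origin_arclength - bs$cuff_end_arclength,
                         tr$length - bs$vessel_origin_arclength)
    tr$nominal_length <- bs$nominal_stent_length
    truths[[bi]] <- tr
  }
  mesh <- mesh_union(meshes, labels = seq_along(meshes) - 1L)
  list(mesh = mesh, parent_truth = pb$truth, branch_truths = truths)
}

angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}
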