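# Independent brute-force oracles, deliberately naive implementations.

# Feret diameters by exhaustive direction sweep (default 0.05-degree
# steps over 180 degrees): width = projection extent on the direction's
# normal; max Feret = max pairwise point distance.
oracle_feret_sweep <- function(points2d, n_dirs = 3600L) {
  d_max <- max(stats::dist(points2d))
  widths <- vapply(seq_len(n_dirs), function(k) {
    th <- (k - 1) * pi / n_dirs
    nrm <- c(-sin(th), cos(th))
    pr <- points2d %*% nrm
    max(pr) - min(pr)
  }, numeric(1))
  c(d_min = min(widths), d_max = d_max)
}

# Slice a mesh with the plane z = z0 by looping over triangle edges --
# independent of the package's segment-chaining slicer.  Returns the raw
# crossing points (x, y).
oracle_slice_z <- function(mesh, z0) {
  v <- mesh$vertices
  f <- mesh$faces
  pts <- list()
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], ]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      za <- tri[e[1], 3] - z0
      zb <- tri[e[2], 3] - z0
      if ((za > 0) != (zb > 0)) {
        t <- za / (za - zb)
        p <- tri[e[1], 1:2] + t * (tri[e[2], 1:2] - tri[e[1], 1:2])
        pts[[length(pts) + 1L]] <- p
      }
    }
  }
  do.call(rbind, pts)
}

# One-way ANOVA from first principles (sums of squares).
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  k <- length(groups)
  n <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, df = c(k - 1, n - k),
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Pooled two-sample t from the textbook formula.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2,
       p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

# Pearson r from moments.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# signed area of a 2-D polygon (positive = counterclockwise)
polygon_area_2d <- function(p2) {
  x <- p2[, 1]; y <- p2[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# random convex polygon (convex hull of random points)
random_convex_polygon <- function(n = 12) {
  p <- cbind(stats::rnorm(n), stats::rnorm(n))
  p[grDevices::chull(p), , drop = FALSE]
}

# rigid motion helpers
rotation_matrix <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * K %*% K
}

transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  surface_mesh(sweep(mesh$vertices %*% t(R), 2, t, "+"), mesh$faces,
               face_labels = mesh$face_labels, clean = FALSE)
}
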