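#' Voxel label map
#'
#' An axis-aligned integer lattice in world millimetre coordinates, the
#' stand-in for a segmented CTA volume.  Voxel centers define sample
#' positions: voxel (i, j, k) sits at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param array 3-D integer array of labels (0 = background).
#' @param spacing mm per axis, length 3 (or scalar), all positive.
#' @param origin world position (mm) of the center of voxel (1, 1, 1).
#' @export
voxel_map <- function(array, spacing, origin = c(0, 0, 0)) {
  if (length(dim(array)) != 3L) stop("array must be 3-D")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(array < 0)) stop("labels must be non-negative integers")
  storage.mode(array) <- "integer"
  structure(list(array = array, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("voxel_map: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(x$array[x$array > 0])
  if (length(tab)) {
    cat("  labels:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

world_to_index <- function(map, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- sweep(sweep(pts, 2, map$origin), 2, map$spacing, "/")
  idx <- round(idx) + 1L
  storage.mode(idx) <- "integer"
  if (nrow(idx) == 1L) idx[1, ] else idx
}

index_to_world <- function(map, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, map$spacing, "*"), 2, map$origin, "+")
}

#' Total labelled voxel volume (mm^3)
#' @param map a [voxel_map()].
#' @param label which label to count; default any non-zero.
#' @export
voxel_volume <- function(map, label = NULL) {
  n <- if (is.null(label)) sum(map$array > 0L) else sum(map$array == label)
  n * prod(map$spacing)
}

#' Euclidean distance transform of the labelled region
#'
#' Distance (mm) from every voxel to the nearest background voxel;
#' background voxels get 0.  Anisotropic spacing is honoured.
#' @param map a [voxel_map()].
#' @return 3-D numeric array of distances.
#' @export
distance_transform <- function(map) {
  d <- dim(map$array)
  out <- edt3d(as.vector(map$array > 0L), as.integer(d), map$spacing)
  array(out, d)
}

#' Read a voxel label map from NIfTI
#'
#' Only axis-aligned affines are accepted (no shear, no oblique
#' orientation): geometry for angle and length measurements must be
#' unambiguous.  Float data containing only integral values is cast.
#'
#' @param path a .nii or .nii.gz file.
#' @export
read_labelmap <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  M <- aff[1:3, 1:3]
  # axis-aligned: exactly one non-zero per row/column
  nz <- abs(M) > 1e-6
  if (any(rowSums(nz) != 1L) || any(colSums(nz) != 1L)) {
    stop("unsupported orientation: only axis-aligned NIfTI affines accepted")
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume")
  if (any(abs(arr - round(arr)) > 1e-6)) {
    stop("NIfTI data is not integer-valued")
  }
  arr <- array(as.integer(round(arr)), dim(arr))
  # reorder axes so the affine becomes diag-positive
  perm <- apply(nz, 2, which)  # world axis for each voxel axis
  if (!identical(sort(perm), 1:3)) {
    stop("unsupported orientation: axes permuted ambiguously")
  }
  arr <- aperm(arr, order(perm))
  M <- M[, order(perm)]
  off <- aff[1:3, 4]
  sp <- diag(M)
  for (ax in 1:3) {
    if (sp[ax] < 0) {
      arr <- flip_axis(arr, ax)
      off[ax] <- off[ax] + sp[ax] * (dim(arr)[ax] - 1L)
      sp[ax] <- -sp[ax]
    }
  }
  voxel_map(arr, spacing = sp, origin = off)
}

flip_axis <- function(arr, ax) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Write a voxel label map to NIfTI
#' @param map a [voxel_map()].
#' @param path destination .nii or .nii.gz path.
#' @export
write_labelmap <- function(map, path) {
  img <- RNifti::asNifti(map$array)
  RNifti::pixdim(img) <- map$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- map$spacing
  aff[1:3, 4] <- map$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rasterize a watertight surface mesh into a voxel label map
#'
#' Each labelled mesh component is filled independently by even-odd
#' in-polygon tests on planar slices through voxel centers, and the
#' component fills are OR-ed, so a branched phantom (union of closed
#' tubes) rasterizes correctly without boolean surface operations.
#'
#' @param mesh a watertight [surface_mesh()] (per component if labelled).
#' @param spacing_mm isotropic voxel spacing, mm.
#' @param margin_mm empty margin added around the mesh (default 2 voxels).
#' @param label label value for inside voxels (default 1).
#' @return a [voxel_map()].
#' @export
voxelize <- function(mesh, spacing_mm, margin_mm = 2 * spacing_mm,
                     label = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0L) stop("empty mesh")
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  lo <- apply(mesh$vertices, 2, min) - margin_mm
  hi <- apply(mesh$vertices, 2, max) + margin_mm
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing_mm)) + 1L)
  origin <- lo
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing_mm
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing_mm
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing_mm
  arr <- array(FALSE, dims)
  comps <- if (is.null(mesh$face_labels)) list(mesh) else {
    lapply(unique(mesh$face_labels), function(l) mesh_component(mesh, l))
  }
  for (cm in comps) {
    zr <- range(cm$vertices[, 3])
    for (kz in which(zs > zr[1] & zs < zr[2])) {
      loops <- plane_loops(cm, c(0, 0, zs[kz]), flatten_z = TRUE)
      if (length(loops) == 0L) next
      inside2d <- matrix(FALSE, dims[1], dims[2])
      for (loop in loops) {
        bx <- range(loop[, 1]); by <- range(loop[, 2])
        ix <- which(xs >= bx[1] & xs <= bx[2])
        iy <- which(ys >= by[1] & ys <= by[2])
        if (!length(ix) || !length(iy)) next
        g <- expand.grid(x = xs[ix], y = ys[iy])
        inp <- point_in_polygon(g$x, g$y, loop[, 1], loop[, 2])
        inside2d[cbind(rep(ix, length(iy)), rep(iy, each = length(ix)))] <-
          xor(inside2d[cbind(rep(ix, length(iy)),
                             rep(iy, each = length(ix)))], inp)
      }
      arr[, , kz] <- arr[, , kz] | inside2d
    }
  }
  voxel_map(array(as.integer(arr) * as.integer(label), dims),
            spacing = spacing_mm, origin = origin)
}

# All closed intersection loops of a mesh with a plane; returns a list of
# 3-D loop matrices (or xy-only when flatten_z, for the z-slice rasterizer).
plane_loops <- function(mesh, plane_point, plane_normal = c(0, 0, 1),
                        flatten_z = FALSE) {
  segs <- plane_segments(mesh, plane_point, plane_normal)
  if (is.null(segs)) return(list())
  loops <- chain_segments(segs)
  if (flatten_z) {
    lapply(loops, function(l) l[, 1:2, drop = FALSE])
  } else loops
}

# Intersect all triangles with a plane; returns list(pts = 2m x 3 matrix
# of segment endpoints, edge_key = length-2m integer key identifying the
# mesh edge each endpoint lies on) or NULL.
plane_segments <- function(mesh, plane_point, plane_normal) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector((v - matrix(plane_point, nrow(v), 3, byrow = TRUE)) %*%
                 plane_normal)
  # nudge exact-zero vertices off the plane for robustness
  eps <- 1e-9 * max(1, max(abs(d)))
  d[d == 0] <- eps
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  cross <- (d1 > 0) + (d2 > 0) + (d3 > 0)
  hit <- which(cross == 1L | cross == 2L)
  if (length(hit) == 0L) return(NULL)
  nv <- nrow(v)
  ends_a <- matrix(0, length(hit), 3)
  ends_b <- matrix(0, length(hit), 3)
  key_a <- numeric(length(hit))
  key_b <- numeric(length(hit))
  edges <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  dmat <- cbind(d1, d2, d3)[hit, , drop = FALSE]
  fh <- f[hit, , drop = FALSE]
  filled <- integer(length(hit))
  for (e in edges) {
    da <- dmat[, e[1]]; db <- dmat[, e[2]]
    crossing <- (da > 0) != (db > 0)
    if (!any(crossing)) next
    t <- da[crossing] / (da[crossing] - db[crossing])
    pa <- v[fh[crossing, e[1]], , drop = FALSE]
    pb <- v[fh[crossing, e[2]], , drop = FALSE]
    pt <- pa + (pb - pa) * t
    i1 <- fh[crossing, e[1]]; i2 <- fh[crossing, e[2]]
    key <- pmin(i1, i2) * (nv + 1) + pmax(i1, i2)
    w <- which(crossing)
    first <- filled[w] == 0L
    ends_a[w[first], ] <- pt[first, , drop = FALSE]
    key_a[w[first]] <- key[first]
    ends_b[w[!first], ] <- pt[!first, , drop = FALSE]
    key_b[w[!first]] <- key[!first]
    filled[w] <- filled[w] + 1L
  }
  ok <- filled == 2L
  list(a = ends_a[ok, , drop = FALSE], b = ends_b[ok, , drop = FALSE],
       ka = key_a[ok], kb = key_b[ok])
}

# Chain plane-intersection segments into closed loops by matching the
# mesh-edge keys of their endpoints (watertight mesh: every key occurs in
# exactly two segments).
chain_segments <- function(segs) {
  ka <- segs$ka; kb <- segs$kb
  n <- length(ka)
  keys <- c(ka, kb)
  pts <- rbind(segs$a, segs$b)
  used <- logical(n)
  loops <- list()
  # for each segment endpoint key, which segments carry it
  seg_of <- split(rep(seq_len(n), 2), keys)
  for (start in seq_len(n)) {
    if (used[start]) next
    loop_pts <- list()
    # walk: enter a segment at one edge-key, exit at the other
    entry <- kb[start]
    used[start] <- TRUE
    loop_pts[[1]] <- segs$b[start, ]
    loop_pts[[2]] <- segs$a[start, ]
    exit_key <- ka[start]
    repeat {
      cands <- seg_of[[as.character(exit_key)]]
      nxt <- cands[!used[cands]]
      if (length(nxt) == 0L) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      if (ka[nxt] == exit_key) {
        loop_pts[[length(loop_pts) + 1L]] <- segs$b[nxt, ]
        exit_key <- kb[nxt]
      } else {
        loop_pts[[length(loop_pts) + 1L]] <- segs$a[nxt, ]
        exit_key <- ka[nxt]
      }
      if (exit_key == entry) break
    }
    if (exit_key == entry && length(loop_pts) >= 4L) {
      # closed: last point duplicates the first conceptually; drop it
      m <- do.call(rbind, loop_pts)
      loops[[length(loops) + 1L]] <- m[-nrow(m), , drop = FALSE]
    }
  }
  loops
}

# Even-odd point-in-polygon (ray casting along +x), vectorized over
# query points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Extract a closed isosurface of a labelled region
#'
#' The binary occupancy of the requested label is smoothed with a 3x3x3
#' box filter (sub-voxel partial-volume estimate) and the 0.5 isosurface
#' is extracted by marching tetrahedra on the voxel-center lattice; the
#' result is a closed triangle mesh in world coordinates.
#'
#' @param map a [voxel_map()].
#' @param label which label to surface (default 1).
#' @param smooth apply the box smoothing (default TRUE; FALSE gives the
#'   raw mid-voxel surface).
#' @return a [surface_mesh()].
#' @export
labelmap_to_surface <- function(map, label = 1L, smooth = TRUE) {
  occ <- map$array == label
  if (!any(occ)) stop("label ", label, " absent from map")
  # pad so the surface closes at the volume border
  d <- dim(occ)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- occ
  f <- if (smooth) box_smooth3(pad) else pad
  # grid coordinates of the padded lattice (voxel centers)
  gx <- map$origin[1] + ((1:(d[1] + 4)) - 3) * map$spacing[1]
  gy <- map$origin[2] + ((1:(d[2] + 4)) - 3) * map$spacing[2]
  gz <- map$origin[3] + ((1:(d[3] + 4)) - 3) * map$spacing[3]
  marching_tetrahedra(f, gx, gy, gz, iso = 0.5)
}

# 3x3x3 box filter via shifted-array accumulation (zero padding).
box_smooth3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    tz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[tx, ty, tz] <- out[tx, ty, tz] + a[sx, sy, sz]
  }
  out / 27
}

# Vectorized marching tetrahedra at a given iso level on a rectilinear
# scalar field.  Returns a welded, outward-oriented surface_mesh.
marching_tetrahedra <- function(f, gx, gy, gz, iso = 0.5) {
  d <- dim(f)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # candidate cubes: any sign change among the 8 corners
  inside <- f > iso
  cs <- inside[-nx, -ny, -nz] | inside[-1, -ny, -nz] |
        inside[-nx, -1, -nz] | inside[-1, -1, -nz] |
        inside[-nx, -ny, -1] | inside[-1, -ny, -1] |
        inside[-nx, -1, -1] | inside[-1, -1, -1]
  ca <- inside[-nx, -ny, -nz] & inside[-1, -ny, -nz] &
        inside[-nx, -1, -nz] & inside[-1, -1, -nz] &
        inside[-nx, -ny, -1] & inside[-1, -ny, -1] &
        inside[-nx, -1, -1] & inside[-1, -1, -1]
  cand <- which(cs & !ca)
  if (length(cand) == 0L) stop("isosurface empty")
  ci <- arrayInd(cand, d - 1L)
  # 8 cube corners, offsets in (x, y, z)
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  # values and positions at the 8 corners for all candidate cubes
  vals <- matrix(0, length(cand), 8)
  px <- matrix(0, length(cand), 8)
  py <- matrix(0, length(cand), 8)
  pz <- matrix(0, length(cand), 8)
  for (cnr in 1:8) {
    ii <- ci[, 1] + corner_off[cnr, 1]
    jj <- ci[, 2] + corner_off[cnr, 2]
    kk <- ci[, 3] + corner_off[cnr, 3]
    vals[, cnr] <- f[cbind(ii, jj, kk)]
    px[, cnr] <- gx[ii]; py[, cnr] <- gy[jj]; pz[, cnr] <- gz[kk]
  }
  # 6-tetrahedra decomposition of the cube (shared main diagonal 1-7)
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tris <- list()
  for (tt in seq_len(nrow(tets))) {
    cn <- tets[tt, ]
    tv <- vals[, cn, drop = FALSE]
    tin <- tv > iso
    code <- tin[, 1] + 2L * tin[, 2] + 4L * tin[, 3] + 8L * tin[, 4]
    for (code_val in 1:14) {
      rows <- which(code == code_val)
      if (length(rows) == 0L) next
      ins <- which(bitwAnd(code_val, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      interp <- function(iA, iB, rws) {
        # point on edge corner[iA]-corner[iB] where f crosses iso
        vA <- tv[rws, iA]; vB <- tv[rws, iB]
        t <- (iso - vA) / (vB - vA)
        cA <- cn[iA]; cB <- cn[iB]
        cbind(px[rws, cA] + t * (px[rws, cB] - px[rws, cA]),
              py[rws, cA] + t * (py[rws, cB] - py[rws, cA]),
              pz[rws, cA] + t * (pz[rws, cB] - pz[rws, cA]))
      }
      if (length(ins) == 1L || length(ins) == 3L) {
        apex <- if (length(ins) == 1L) ins else outs
        base <- setdiff(1:4, apex)
        p1 <- interp(apex, base[1], rows)
        p2 <- interp(apex, base[2], rows)
        p3 <- interp(apex, base[3], rows)
        # orient outward: normal should point from inside corner to outside
        ref <- if (length(ins) == 1L) {
          cbind(px[rows, cn[apex]], py[rows, cn[apex]], pz[rows, cn[apex]])
        } else {
          (cbind(px[rows, cn[base[1]]], py[rows, cn[base[1]]],
                 pz[rows, cn[base[1]]]) +
           cbind(px[rows, cn[base[2]]], py[rows, cn[base[2]]],
                 pz[rows, cn[base[2]]]) +
           cbind(px[rows, cn[base[3]]], py[rows, cn[base[3]]],
                 pz[rows, cn[base[3]]])) / 3
        }
        tris[[length(tris) + 1L]] <- orient_tris(p1, p2, p3, ref)
      } else {
        # two in, two out: quad from the four crossing edges
        p11 <- interp(ins[1], outs[1], rows)
        p12 <- interp(ins[1], outs[2], rows)
        p21 <- interp(ins[2], outs[1], rows)
        p22 <- interp(ins[2], outs[2], rows)
        refin <- (cbind(px[rows, cn[ins[1]]], py[rows, cn[ins[1]]],
                        pz[rows, cn[ins[1]]]) +
                  cbind(px[rows, cn[ins[2]]], py[rows, cn[ins[2]]],
                        pz[rows, cn[ins[2]]])) / 2
        tris[[length(tris) + 1L]] <- orient_tris(p11, p12, p22, refin)
        tris[[length(tris) + 1L]] <- orient_tris(p11, p22, p21, refin)
      }
    }
  }
  allp <- do.call(rbind, tris)
  ntri <- nrow(allp) / 3
  verts <- allp
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  mesh_weld(surface_mesh(verts, faces, clean = TRUE), tol = 1e-7)
}

# Stack triangles (p1, p2, p3 row-wise per triangle) flipped so normals
# point away from the inside reference points.
orient_tris <- function(p1, p2, p3, ref_inside) {
  e1 <- p2 - p1
  e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  cen <- (p1 + p2 + p3) / 3
  dir <- cen - ref_inside
  dp <- nx * dir[, 1] + ny * dir[, 2] + nz * dir[, 3]
  flip <- dp < 0
  p2f <- p2; p3f <- p3
  p2f[flip, ] <- p3[flip, , drop = FALSE]
  p3f[flip, ] <- p2[flip, , drop = FALSE]
  out <- matrix(0, 3 * nrow(p1), 3)
  out[seq(1, nrow(out), 3), ] <- p1
  out[seq(2, nrow(out), 3), ] <- p2f
  out[seq(3, nrow(out), 3), ] <- p3f
  out
}
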