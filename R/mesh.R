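#' Triangulated surface mesh
#'
#' Container for a triangle mesh in world millimetre coordinates, the
#' common currency between the phantom generator, the voxelizer, the
#' cross-section slicer and the file readers/writers.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param face_labels optional integer vector, one label per face
#'   (components of a branched phantom carry distinct labels).
#' @param clean drop degenerate (zero-area) triangles and unreferenced
#'   vertices.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, face_labels = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (!is.null(face_labels) && length(face_labels) != nrow(faces)) {
    stop("face_labels must have one entry per face")
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      face_labels = face_labels),
                 class = "surface_mesh")
  if (clean && nrow(faces) > 0L) m <- mesh_clean(m)
  m
}

# Remove zero-area faces (repeated indices or collinear vertices).
mesh_clean <- function(mesh, area_tol = 1e-12) {
  f <- mesh$faces
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  a <- triangle_areas(mesh)
  keep <- !degen & a > area_tol
  mesh$faces <- f[keep, , drop = FALSE]
  if (!is.null(mesh$face_labels)) mesh$face_labels <- mesh$face_labels[keep]
  mesh
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Signed volume by the divergence theorem; meaningful for watertight,
#' consistently oriented meshes.  For a multi-component mesh the component
#' volumes add (overlap counted per component).
#' @param mesh a `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  # sum of signed tetrahedron volumes against the origin
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
         a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
         a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(det)) / 6
}

#' Check that every edge is shared by exactly two faces
#'
#' @param mesh a `surface_mesh`.
#' @param per_component when the mesh carries face labels, audit each
#'   labelled component separately (a branched phantom is a union of
#'   individually closed tubes).
#' @return logical.
#' @export
is_watertight <- function(mesh, per_component = TRUE) {
  if (per_component && !is.null(mesh$face_labels)) {
    labs <- unique(mesh$face_labels)
    return(all(vapply(labs, function(l) {
      is_watertight(mesh_component(mesh, l), per_component = FALSE)
    }, logical(1))))
  }
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Extract one labelled component of a mesh
#' @param mesh a `surface_mesh` with face labels.
#' @param label the component label to keep.
#' @export
mesh_component <- function(mesh, label) {
  if (is.null(mesh$face_labels)) {
    if (identical(label, 0L) || identical(label, 0)) return(mesh)
    stop("mesh carries no face labels")
  }
  keep <- mesh$face_labels == label
  if (!any(keep)) stop("no faces with label ", label)
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               clean = FALSE)
}

#' Merge meshes into one labelled mesh
#' @param meshes list of `surface_mesh` objects.
#' @param labels integer label per input mesh.
#' @export
mesh_union <- function(meshes, labels = seq_along(meshes) - 1L) {
  vs <- lapply(meshes, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  fs <- mapply(function(m, o) m$faces + o, meshes, off[-length(off)],
               SIMPLIFY = FALSE)
  fl <- unlist(mapply(function(m, l) rep(l, nrow(m$faces)), meshes, labels,
                      SIMPLIFY = FALSE))
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs), face_labels = fl,
               clean = FALSE)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.null(x$face_labels)) {
    cat(sprintf(", %d components", length(unique(x$face_labels))))
  }
  cat(sprintf("\n  area %.2f mm^2", mesh_area(x)))
  if (nrow(x$faces) > 0 && is_watertight(x)) {
    cat(sprintf(", enclosed volume %.2f mm^3 (watertight)", mesh_volume(x)))
  }
  cat("\n")
  invisible(x)
}

# Weld vertices closer than tol (used after isosurface extraction).
mesh_weld <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(remap[mesh$faces], ncol = 3)
  surface_mesh(newv, newf, face_labels = mesh$face_labels, clean = TRUE)
}
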