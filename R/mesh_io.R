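#' Read a triangle mesh from STL, PLY or OBJ
#'
#' ASCII variants of the three formats are supported; the format is chosen
#' by file extension.  Binary STL is detected and read as well.  Degenerate
#' triangles are dropped on load.
#'
#' @param path file path ending in .stl, .ply or .obj.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unknown mesh extension '", ext, "' for ", path))
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a [surface_mesh()].
#' @param path destination; extension selects the format.
#' @param digits coordinate precision written to file.
#' @export
write_mesh <- function(mesh, path, digits = 9) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, digits),
         ply = write_ply(mesh, path, digits),
         obj = write_obj(mesh, path, digits),
         stop("unknown mesh extension '", ext, "' for ", path))
  invisible(path)
}

fmt_num <- function(x, digits) {
  formatC(x, digits = digits, format = "g")
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 6L)
  if (!identical(rawToChar(head[1:5]), "solid")) return(read_stl_binary(path))
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    # ASCII header but maybe binary payload, or malformed
    m <- try(read_stl_binary(path), silent = TRUE)
    if (!inherits(m, "try-error")) return(m)
    stop("malformed STL file: ", path)
  }
  coords <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+",
                                                         "", vl)),
                                              "\\s+"))),
                   ncol = 3, byrow = TRUE)
  if (anyNA(coords)) stop("malformed STL file: ", path)
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  mesh_weld(surface_mesh(coords, faces, clean = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(ntri) || ntri <= 0L || 84 + ntri * 50 != file.size(path)) {
    stop("malformed STL file: ", path)
  }
  rec <- readBin(con, "raw", n = ntri * 50L)
  rec <- matrix(rec, nrow = 50L)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4L,
                  n = 12L * ntri, endian = "little")
  vals <- matrix(vals, nrow = 12L)
  coords <- matrix(as.vector(vals[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
  mesh_weld(surface_mesh(coords, faces, clean = TRUE))
}

write_stl <- function(mesh, path, digits) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  tri <- vapply(seq_len(nrow(f)), function(i) {
    p <- v[f[i, ], , drop = FALSE]
    paste0("facet normal ", paste(fmt_num(n[i, ], digits), collapse = " "),
           "\n outer loop\n",
           paste0("  vertex ",
                  apply(p, 1, function(r) paste(fmt_num(r, digits),
                                                collapse = " ")),
                  collapse = "\n"),
           "\n endloop\nendfacet")
  }, character(1))
  writeLines(c("solid stentgeom", tri, "endsolid stentgeom"), path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop("malformed PLY file: ", path)
  }
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY file (no end_header): ", path)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header))) {
    stop("only ASCII PLY supported: ", path)
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- body[seq_len(nv)]
  fl <- body[nv + seq_len(nf)]
  vs <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                        function(x) x[1:3]))),
               ncol = 3, byrow = TRUE)
  fparsed <- lapply(strsplit(trimws(fl), "\\s+"), as.integer)
  if (any(vapply(fparsed, function(x) x[1] != 3L, logical(1)))) {
    stop("non-triangular PLY faces not supported: ", path)
  }
  fs <- matrix(unlist(lapply(fparsed, function(x) x[2:4])) + 1L,
               ncol = 3, byrow = TRUE)
  if (anyNA(vs) || anyNA(fs)) stop("malformed PLY file: ", path)
  surface_mesh(vs, fs, clean = TRUE)
}

write_ply <- function(mesh, path, digits) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- paste(fmt_num(v[, 1], digits), fmt_num(v[, 2], digits),
                  fmt_num(v[, 3], digits))
  flines <- paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) {
    stop("malformed OBJ file: ", path)
  }
  vs <- matrix(as.numeric(unlist(lapply(strsplit(trimws(sub("^v\\s+", "",
                                                            vl)), "\\s+"),
                                        function(x) x[1:3]))),
               ncol = 3, byrow = TRUE)
  # face entries may be v, v/vt, v/vt/vn; keep the vertex index
  fidx <- lapply(strsplit(trimws(sub("^f\\s+", "", fl)), "\\s+"),
                 function(x) as.integer(sub("/.*$", "", x)))
  if (any(vapply(fidx, length, integer(1)) != 3L)) {
    stop("non-triangular OBJ faces not supported: ", path)
  }
  fs <- matrix(unlist(fidx), ncol = 3, byrow = TRUE)
  if (anyNA(vs) || anyNA(fs)) stop("malformed OBJ file: ", path)
  surface_mesh(vs, fs, clean = TRUE)
}

write_obj <- function(mesh, path, digits) {
  v <- mesh$vertices
  f <- mesh$faces
  vlines <- paste("v", fmt_num(v[, 1], digits), fmt_num(v[, 2], digits),
                  fmt_num(v[, 3], digits))
  flines <- paste("f", f[, 1], f[, 2], f[, 3])
  writeLines(c(vlines, flines), path)
}
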