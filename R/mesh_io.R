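#' Triangle mesh container
#'
#' @param vertices Numeric matrix \code{m x 3}.
#' @param faces Integer matrix \code{f x 3} of 1-based vertex indices.
#' @return A \code{tri_mesh} object.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("tri_mesh: vertices must be m x 3")
  if (ncol(faces) != 3L) stop("tri_mesh: faces must be f x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("tri_mesh: face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, watertight=%s\n",
              nrow(x$vertices), nrow(x$faces), is_watertight(x)))
  invisible(x)
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh A \code{tri_mesh}.
#' @return Logical flag.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Surface area of a triangle mesh
#' @param mesh A \code{tri_mesh}.
#' @return Scalar area.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' consistently outward-oriented meshes.
#'
#' @param mesh A \code{tri_mesh}.
#' @return Scalar volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

#' Axis-aligned bounding box
#' @param mesh A \code{tri_mesh}.
#' @return 2 x 3 matrix (min row, max row).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Load a triangle mesh from PLY, OBJ or STL
#'
#' Supports ASCII and binary-little-endian PLY, OBJ (v/f lines, polygonal
#' faces fan-triangulated) and ASCII STL. Degenerate faces (repeated vertex
#' indices) are dropped with a warning; non-watertight input is flagged with
#' a warning but still returned, since the downstream sign regularization is
#' designed to cope with imperfectly closed surfaces.
#'
#' @param path File path; format from the extension.
#' @return A \code{tri_mesh}.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl_ascii(path),
    stop("read_mesh: unsupported extension '", ext, "' (need ply/obj/stl)")
  )
  deg <- mesh$faces[, 1] == mesh$faces[, 2] |
         mesh$faces[, 2] == mesh$faces[, 3] |
         mesh$faces[, 1] == mesh$faces[, 3]
  if (any(deg)) {
    warning("read_mesh: removed ", sum(deg), " degenerate face(s)")
    mesh <- tri_mesh(mesh$vertices, mesh$faces[!deg, , drop = FALSE])
  }
  if (!is_watertight(mesh))
    warning("read_mesh: mesh is not watertight")
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("read_obj: no vertices/faces in ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1))
    for (t in seq_len(length(idx) - 2))  # fan triangulation
      faces[[length(faces) + 1L]] <- c(idx[1], idx[t + 1], idx[t + 2])
  }
  tri_mesh(verts, do.call(rbind, faces))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 200) stop("read_ply: header not terminated")
  }
  fmt <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", header, value = TRUE)[1]))
  # vertex properties (assume x,y,z leading floats; skip extras)
  vlines <- header[grep("element vertex", header) + seq_len(100)]
  vprops <- grep("^property", header, value = TRUE)
  # count scalar vertex properties before the face element
  iv <- grep("element vertex", header)
  ifc <- grep("element face", header)
  nprop <- sum(grepl("^property", header[iv:ifc]))
  if (binary) {
    verts <- matrix(0, nv, 3)
    extra <- nprop - 3L
    for (i in seq_len(nv)) {
      vals <- readBin(con, "numeric", n = nprop, size = 4, endian = "little")
      verts[i, ] <- vals[1:3]
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      faces[i, ] <- idx[1:3] + 1L
    }
  } else {
    txt <- readLines(con)
    vtok <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    verts <- do.call(rbind, lapply(vtok, function(x) as.numeric(x[1:3])))
    ftok <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(ftok, function(x) as.integer(x[2:4]) + 1L))
  }
  tri_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  if (nrow(coords) %% 3 != 0) stop("read_stl_ascii: vertex count not * 3")
  key <- apply(coords, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' PLY is written binary little-endian by default (ASCII via
#' \code{binary = FALSE}); OBJ and STL are ASCII.
#'
#' @param mesh A \code{tri_mesh}.
#' @param path Output path; format from the extension.
#' @param binary Write binary PLY (default TRUE; ignored for OBJ/STL).
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary),
    stl = write_stl_ascii(mesh, path),
    stop("write_mesh: unsupported extension '", ext, "'")
  )
  invisible(path)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
    # interleave count byte and 0-based indices per face
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    a <- v[f[2], ] - v[f[1], ]
    b <- v[f[3], ] - v[f[1], ]
    nrm <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(sprintf("facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
               con)
    writeLines(" outer loop", con)
    for (q in f)
      writeLines(sprintf("  vertex %.9g %.9g %.9g", v[q, 1], v[q, 2], v[q, 3]),
                 con)
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

#' Uniformly rescale a closed mesh to a target enclosed volume
#'
#' Scales the mesh about its volume centroid by
#' \code{(target_volume / V)^(1/3)} and places the centroid at
#' \code{center}. Normalizing on the surface, before voxelization, preserves
#' thin features (apices) that a voxel-level rescale of an already
#' voxelized small shape would have lost.
#'
#' @param mesh A closed \code{tri_mesh}.
#' @param target_volume Target enclosed volume.
#' @param center Where to place the volume centroid (default cube center).
#' @return The rescaled \code{tri_mesh}.
#' @export
rescale_mesh_to_volume <- function(mesh, target_volume,
                                   center = c(0.5, 0.5, 0.5)) {
  V <- mesh_volume(mesh)
  if (V <= 0) stop("rescale_mesh_to_volume: mesh has no enclosed volume")
  s <- (target_volume / V)^(1 / 3)
  cen <- mesh_volume_centroid(mesh)
  verts <- sweep(mesh$vertices, 2, cen) * s
  # place the bounding-box midpoint at `center` (tap roots are bottom-heavy
  # in extent but top-heavy in mass, so centroid placement could push the
  # apex out of the domain)
  mid <- (apply(verts, 2, min) + apply(verts, 2, max)) / 2
  verts <- sweep(sweep(verts, 2, mid), 2, center, "+")
  if (min(verts) < 0.01 || max(verts) > 0.99)
    stop("rescale_mesh_to_volume: scaled mesh leaves the domain; ",
         "use a smaller target volume")
  tri_mesh(verts, mesh$faces)
}

# centroid of the enclosed volume by the divergence theorem
mesh_volume_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  num <- colSums((p1 + p2 + p3) / 4 * det6)
  num / sum(det6)
}

#' Icosphere triangulation
#'
#' Subdivided icosahedron; handy as an analytic test fixture and as the
#' direction set of the synthetic root generator.
#'
#' @param subdiv Number of 4-to-1 subdivisions (0 = icosahedron).
#' @param radius Sphere radius.
#' @param center Sphere center (length 3).
#' @return A watertight \code{tri_mesh}.
#' @export
icosphere <- function(subdiv = 3L, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(cc, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  verts <- sweep(v * radius, 2, center, "+")
  tri_mesh(verts, f)
}
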