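#' Triangle surface mesh
#'
#' The basic geometric container of the package: an indexed triangle mesh
#' with vertex coordinates in millimetres, and optionally one RGB colour per
#' vertex (0--255 integers, used for loading colour maps).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangular face, three 1-based
#'   vertex indices per row.
#' @param colors optional integer matrix (same row count as `vertices`,
#'   3 columns, values in 0--255).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite values")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, V]")
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen))
      stop("degenerate face (repeated vertex) at face ", which(degen)[1])
  } else {
    faces <- matrix(integer(0), 0L, 3L)
  }
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
      stop("colors must be a V x 3 matrix")
    if (min(colors) < 0L || max(colors) > 255L)
      stop("colors must lie in 0..255")
  }
  structure(list(vertices = unname(vertices), faces = unname(faces),
                 colors = if (is.null(colors)) NULL else unname(colors)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", per-vertex RGB"))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a [triangle_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# unique undirected edge key; V-safe for meshes < ~3e9 edges
.edge_keys <- function(faces) {
  a <- pmin(faces[, c(1, 2, 3)], faces[, c(2, 3, 1)])
  b <- pmax(faces[, c(1, 2, 3)], faces[, c(2, 3, 1)])
  list(a = as.vector(a), b = as.vector(b),
       key = (as.numeric(as.vector(a)) - 1) * 2^31 + as.numeric(as.vector(b)))
}

#' Undirected edge list of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return integer matrix E x 2, each row an edge (i < j), no duplicates.
#' @export
mesh_edges <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(matrix(integer(0), 0L, 2L))
  ek <- .edge_keys(mesh$faces)
  keep <- !duplicated(ek$key)
  cbind(ek$a[keep], ek$b[keep])
}

#' Euler characteristic V - E + F
#' @param mesh a [triangle_mesh()].
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + n_faces(mesh)
}

# per-edge incident face count, in the order of mesh_edges()
.edge_face_count <- function(mesh) {
  ek <- .edge_keys(mesh$faces)
  tab <- table(ek$key)
  keep <- !duplicated(ek$key)
  as.integer(tab[as.character(ek$key[keep])])
}

#' Check that every edge borders at most two faces
#' @param mesh a [triangle_mesh()].
#' @return logical.
#' @export
is_edge_manifold <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(TRUE)
  ek <- .edge_keys(mesh$faces)
  max(tabulate(match(ek$key, unique(ek$key)))) <= 2L
}

#' Per-face and per-vertex normals
#'
#' Face normals are unit normals of each triangle (right-hand rule on the
#' vertex order); vertex normals are area-weighted averages of incident face
#' normals, normalised.
#'
#' @param mesh a [triangle_mesh()].
#' @return F x 3 (`face_normals`) or V x 3 (`vertex_normals`) matrix.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

#' @rdname face_normals
#' @export
vertex_normals <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted (unnormalised)
  idx <- as.vector(f)
  out <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    s <- rowsum(rep(n[, k], 3), idx)
    out[as.integer(rownames(s)), k] <- s
  }
  len <- sqrt(rowSums(out^2))
  out / pmax(len, .Machine$double.eps)
}

#' Centroid size of a mesh or point configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances of all points from their centroid. Computed over
#' all vertices, so uniform scaling by `s` multiplies it by `s`.
#'
#' @param x a [triangle_mesh()] or a numeric matrix of points (rows).
#' @return centroid size in mm.
#' @export
centroid_size <- function(x) {
  v <- if (inherits(x, "triangle_mesh")) x$vertices else as.matrix(x)
  if (nrow(v) < 1L) stop("at least one vertex required")
  ctr <- colMeans(v)
  sqrt(sum(sweep(v, 2, ctr)^2))
}
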