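#' Closest points on a mesh surface
#'
#' For each query point, the exact closest point on any triangle of the
#' target mesh (point-to-triangle projection accelerated by a bounding
#' volume hierarchy), not merely the nearest vertex. Ties are broken toward
#' the lowest face index.
#'
#' @param points numeric matrix of query points (rows, mm).
#' @param mesh the target [triangle_mesh()].
#' @return a list with `point` (n x 3 closest points), `distance` (n), and
#'   `face` (n, 1-based face index).
#' @export
closest_on_surface <- function(points, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (n_faces(mesh) == 0L) stop("target mesh has no faces")
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .cpp_closest_on_mesh(mesh$vertices, mesh$faces, points)
}

#' Vertex-to-surface distance report between two meshes
#'
#' For every vertex of `model`, the distance to the closest point on the
#' surface of `target`; the mean and maximum are reported. If both landmark
#' sets are supplied, the mean distance over their shared landmark names is
#' reported as well. All distances are in mm.
#'
#' @param model a [triangle_mesh()] whose vertices are measured.
#' @param target the reference surface ([triangle_mesh()]).
#' @param model_landmarks,target_landmarks optional [landmark_set()]s; the
#'   landmark distance is averaged over exactly the shared names.
#' @return a one-row tibble (class `mesh_distance_report`) with
#'   `mean_point_to_surface_distance`, `max_point_to_surface_distance`, and
#'   `mean_landmark_distance` (NA when landmarks are not supplied).
#' @export
surface_distance <- function(model, target,
                             model_landmarks = NULL, target_landmarks = NULL) {
  stopifnot(inherits(model, "triangle_mesh"), inherits(target, "triangle_mesh"))
  if (n_vertices(model) == 0L) stop("model mesh is empty")
  if (n_faces(target) == 0L) stop("target mesh is empty")
  cp <- closest_on_surface(model$vertices, target)
  lmd <- NA_real_
  if (!is.null(model_landmarks) && !is.null(target_landmarks)) {
    shared <- intersect(landmark_names(model_landmarks),
                        landmark_names(target_landmarks))
    if (length(shared) == 0L) stop("no shared landmark names")
    d <- landmark_points(model_landmarks)[shared, , drop = FALSE] -
      landmark_points(target_landmarks)[shared, , drop = FALSE]
    lmd <- mean(sqrt(rowSums(d^2)))
  }
  out <- tibble::tibble(
    mean_point_to_surface_distance = mean(cp$distance),
    max_point_to_surface_distance = max(cp$distance),
    mean_landmark_distance = lmd)
  class(out) <- c("mesh_distance_report", class(out))
  out
}

#' Mirror-symmetrize a paired mesh about a plane
#'
#' Used during template construction: each vertex is replaced by the average
#' of itself and the reflection of its mirror partner, and midline vertices
#' (paired with themselves) are projected onto the plane. The result is
#' exactly reflection-symmetric under the pairing.
#'
#' @param mesh a [triangle_mesh()].
#' @param pairs integer vector of length V; `pairs[i]` is the index of the
#'   mirror partner of vertex `i` (itself for midline vertices). Must be an
#'   involution.
#' @param plane list with unit `normal` (length-3) and `offset` scalar so the
#'   plane is `normal . x = offset`; default the x = 0 midsagittal plane.
#' @return the symmetrized [triangle_mesh()].
#' @export
symmetrize <- function(mesh, pairs,
                       plane = list(normal = c(1, 0, 0), offset = 0)) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (missing(pairs) || is.null(pairs)) stop("a mirror pair map is required")
  v <- mesh$vertices
  if (length(pairs) != nrow(v)) stop("pair map length must equal vertex count")
  if (!all(pairs[pairs] == seq_along(pairs)))
    stop("pair map must be an involution")
  n <- plane$normal / sqrt(sum(plane$normal^2))
  d <- plane$offset
  reflect <- function(x) x - 2 * outer(as.vector(x %*% n) - d, n)
  vm <- reflect(v[pairs, , drop = FALSE])
  out <- (v + vm) / 2
  mid <- pairs == seq_along(pairs)
  if (any(mid)) {
    x <- out[mid, , drop = FALSE]
    out[mid, ] <- x - outer(as.vector(x %*% n) - d, n)
  }
  triangle_mesh(out, mesh$faces, mesh$colors)
}
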