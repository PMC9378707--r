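#' Head-oriented (Frankfurt-based) coordinate system
#'
#' Builds the anatomical frame from four landmarks. The X axis runs from
#' the left to the right porion (X+ toward the right porion); the X-Z plane
#' is the Frankfurt horizontal plane through both porions and the left
#' orbitale; Z is the in-plane direction orthogonal to X, signed so the
#' nasion lies forward (Z > 0); Y completes a right-handed basis and points
#' upward. The origin is the midpoint of the porions (the intersection of
#' the median, Frankfurt and coronal planes). The nasion is used only to
#' disambiguate signs; its residual X offset is reported as a QC value, not
#' forced to zero.
#'
#' @param landmarks a [landmark_set()] containing at least `porion_r`,
#'   `porion_l`, `orbitale_l` and `nasion`.
#' @return an object of class `head_frame`: list with `origin` (mm),
#'   `axes` (3 x 3 orthonormal matrix with columns X, Y, Z, det = +1) and
#'   `nasion_x_offset` (mm, QC).
#' @export
compute_head_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  need <- c("porion_r", "porion_l", "orbitale_l", "nasion")
  miss <- setdiff(need, landmark_names(landmarks))
  if (length(miss))
    stop("missing required landmarks: ", paste(miss, collapse = ", "))
  p <- landmark_points(landmarks)
  pr <- p["porion_r", ]; pl <- p["porion_l", ]
  ol <- p["orbitale_l", ]; na_ <- p["nasion", ]

  dx <- pr - pl
  if (sqrt(sum(dx^2)) < 1e-9) stop("porions coincide")
  X <- dx / sqrt(sum(dx^2))
  v <- ol - pl
  nrm <- c(X[2] * v[3] - X[3] * v[2],
           X[3] * v[1] - X[1] * v[3],
           X[1] * v[2] - X[2] * v[1])          # Frankfurt plane normal
  if (sqrt(sum(nrm^2)) < 1e-9)
    stop("orbitale is collinear with the porions")
  nrm <- nrm / sqrt(sum(nrm^2))
  Z <- c(nrm[2] * X[3] - nrm[3] * X[2],
         nrm[3] * X[1] - nrm[1] * X[3],
         nrm[1] * X[2] - nrm[2] * X[1])        # in-plane, orthogonal to X
  origin <- (pr + pl) / 2
  if (sum(Z * (na_ - origin)) < 0) Z <- -Z     # nasion forward
  Y <- c(Z[2] * X[3] - Z[3] * X[2],
         Z[3] * X[1] - Z[1] * X[3],
         Z[1] * X[2] - Z[2] * X[1])            # = Z x X, right-handed
  if (sum(Y * (na_ - origin)) < 0)
    warning("nasion lies below the Frankfurt plane; Y+ may not be anatomical up")
  axes <- cbind(X = X, Y = Y, Z = Z)
  structure(list(origin = origin, axes = axes,
                 nasion_x_offset = sum(X * (na_ - origin))),
            class = "head_frame")
}

#' @export
print.head_frame <- function(x, ...) {
  cat("<head_frame> origin:", sprintf("%.3f", x$origin), "\n")
  invisible(x)
}

#' Express a mesh and its landmarks in a head frame
#'
#' Applies the rigid change of coordinates `v -> t(axes) %*% (v - origin)`:
#' distances are preserved exactly, the right porion maps onto the +X axis,
#' and the porion midpoint becomes the origin.
#'
#' @param mesh a [triangle_mesh()] (or NULL).
#' @param landmarks a [landmark_set()] transformed along with the mesh.
#' @param frame a `head_frame` from [compute_head_frame()].
#' @return list with transformed `mesh` and `landmarks`.
#' @export
to_head_frame <- function(mesh, landmarks, frame) {
  stopifnot(inherits(frame, "head_frame"))
  tf <- function(pts) sweep(pts, 2, frame$origin) %*% frame$axes
  out_mesh <- NULL
  if (!is.null(mesh)) {
    stopifnot(inherits(mesh, "triangle_mesh"))
    out_mesh <- triangle_mesh(tf(mesh$vertices), mesh$faces, mesh$colors)
  }
  out_lms <- NULL
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "landmark_set"))
    out_lms <- landmark_set(tf(landmark_points(landmarks)),
                            names = landmark_names(landmarks),
                            schema = landmarks$schema)
  }
  list(mesh = out_mesh, landmarks = out_lms)
}

#' Serialize / read a head frame as JSON
#' @param frame a `head_frame`.
#' @param path file path.
#' @return `read_head_frame` returns a `head_frame`.
#' @export
write_head_frame <- function(frame, path) {
  jsonlite::write_json(list(origin = frame$origin,
                            x = frame$axes[, 1], y = frame$axes[, 2],
                            z = frame$axes[, 3],
                            nasion_x_offset = frame$nasion_x_offset),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_head_frame
#' @export
read_head_frame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(origin = j$origin,
                 axes = cbind(X = j$x, Y = j$y, Z = j$z),
                 nasion_x_offset = j$nasion_x_offset),
            class = "head_frame")
}
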