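#' Least-squares rigid (or similarity) alignment of landmark sets
#'
#' Closed-form Kabsch/Umeyama solution over the landmark pairs shared by
#' name: the proper rotation (never a reflection), translation, and
#' optionally a uniform scale, minimising the sum of squared distances
#' between corresponding landmarks.
#'
#' @param source_lms,target_lms [landmark_set()]s; the transform maps
#'   source onto target.
#' @param allow_scale estimate a uniform scale (default FALSE: rigid).
#' @return an object of class `rigid_transform`: list with `R` (3 x 3,
#'   det = +1), `t` (length 3), `s` (scalar), `rmsd` (mm over the shared
#'   landmarks) and `n` (number of pairs used).
#' @export
rigid_landmark_align <- function(source_lms, target_lms, allow_scale = FALSE) {
  shared <- intersect(landmark_names(source_lms), landmark_names(target_lms))
  if (length(shared) < 3L) stop("need at least 3 shared landmarks")
  A <- landmark_points(source_lms)[shared, , drop = FALSE]
  B <- landmark_points(target_lms)[shared, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))          # 3 x 3
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("landmarks are collinear; rotation is undetermined")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- 1
  if (allow_scale) {
    varA <- sum(A0^2)
    if (varA < 1e-12) stop("degenerate source landmarks")
    s <- sum(sv$d * diag(D)) / varA
  }
  t <- cb - s * as.vector(R %*% ca)
  res <- B - (s * A %*% t(R) + rep(t, each = nrow(A)))
  structure(list(R = R, t = t, s = s,
                 rmsd = sqrt(mean(rowSums(res^2))), n = length(shared)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> scale %.6g, rmsd %.4g mm over %d landmarks\n",
              x$s, x$rmsd, x$n))
  invisible(x)
}

#' Apply a rigid/similarity transform
#'
#' @param x a [triangle_mesh()], [landmark_set()] or point matrix.
#' @param transform a `rigid_transform` (or list with `R`, `t`, `s`).
#' @return the transformed object of the same class.
#' @export
apply_transform <- function(x, transform) {
  s <- if (is.null(transform$s)) 1 else transform$s
  tf <- function(p) s * p %*% t(transform$R) + rep(transform$t, each = nrow(p))
  if (inherits(x, "triangle_mesh"))
    return(triangle_mesh(tf(x$vertices), x$faces, x$colors))
  if (inherits(x, "landmark_set"))
    return(landmark_set(tf(landmark_points(x)), names = landmark_names(x),
                        schema = x$schema))
  tf(as.matrix(x))
}
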