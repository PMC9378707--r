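#' Loop subdivision of a triangle mesh
#'
#' One pass of Loop's subdivision scheme: a new vertex is inserted on every
#' edge (so V' = V + E) and every face splits into four (F' = 4F). Interior
#' edge vertices use the 3/8-3/8-1/8-1/8 mask, boundary edge vertices the
#' midpoint rule; repositioned original vertices use Loop's valence-dependent
#' beta weights in the interior and the 1/8-3/4-1/8 crease rule on
#' boundaries. Original vertices keep their indices (1..V); edge vertices are
#' appended in the order of [mesh_edges()].
#'
#' @param mesh an edge-manifold [triangle_mesh()] (boundaries allowed).
#' @return the subdivided [triangle_mesh()].
#' @export
loop_subdivide <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) stop("mesh has no faces")
  nv <- nrow(v); nf <- nrow(f)

  ek <- .edge_keys(f)                      # 3F directed occurrences
  ukey <- unique(ek$key)
  eid <- match(ek$key, ukey)               # edge id per face-edge slot
  ne <- length(ukey)
  ecount <- tabulate(eid, ne)
  if (any(ecount > 2L))
    stop("non-manifold edge (more than two incident faces)")
  first <- match(seq_len(ne), eid)
  ea <- ek$a[first]; eb <- ek$b[first]     # edge endpoints (a < b)
  boundary_edge <- ecount == 1L

  # opposite vertex of each face-edge occurrence
  opp <- c(f[, 3], f[, 1], f[, 2])         # edges (1,2),(2,3),(3,1)
  opp_sum <- rowsum(v[opp, , drop = FALSE], eid)
  opp_sum <- opp_sum[order(as.integer(rownames(opp_sum))), , drop = FALSE]

  # odd (edge) vertices
  emid <- matrix(0, ne, 3)
  ends <- v[ea, , drop = FALSE] + v[eb, , drop = FALSE]
  emid[boundary_edge, ] <- ends[boundary_edge, , drop = FALSE] / 2
  int <- !boundary_edge
  emid[int, ] <- 0.375 * ends[int, , drop = FALSE] +
    0.125 * opp_sum[int, , drop = FALSE]

  # even (original) vertices
  deg <- tabulate(c(ea, eb), nv)
  nb_sum <- matrix(0, nv, 3)
  s <- rowsum(rbind(v[eb, , drop = FALSE], v[ea, , drop = FALSE]), c(ea, eb))
  nb_sum[as.integer(rownames(s)), ] <- s
  is_bnd_v <- rep(FALSE, nv)
  is_bnd_v[c(ea[boundary_edge], eb[boundary_edge])] <- TRUE

  n <- pmax(deg, 3L)
  beta <- (1 / n) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / n))^2)
  beta[deg == 0L] <- 0       # isolated vertices keep their position
  vnew <- (1 - deg * beta) * v + beta * nb_sum

  if (any(is_bnd_v)) {
    bsum <- matrix(0, nv, 3)
    bdeg <- integer(nv)
    bea <- ea[boundary_edge]; beb <- eb[boundary_edge]
    s <- rowsum(rbind(v[beb, , drop = FALSE], v[bea, , drop = FALSE]),
                c(bea, beb))
    idx <- as.integer(rownames(s))
    bsum[idx, ] <- s
    bdeg[idx] <- tabulate(c(bea, beb), nv)[idx]
    if (any(bdeg[is_bnd_v] != 2L))
      stop("boundary vertex with valence != 2 boundary edges (non-manifold)")
    vnew[is_bnd_v, ] <- 0.75 * v[is_bnd_v, , drop = FALSE] +
      0.125 * bsum[is_bnd_v, , drop = FALSE]
  }

  everts <- nv + matrix(eid, nf, 3)        # columns: edge(1,2), (2,3), (3,1)
  faces_new <- rbind(
    cbind(f[, 1], everts[, 1], everts[, 3]),
    cbind(f[, 2], everts[, 2], everts[, 1]),
    cbind(f[, 3], everts[, 3], everts[, 2]),
    everts)

  colors <- NULL
  if (!is.null(mesh$colors)) {
    ec <- (mesh$colors[ea, , drop = FALSE] + mesh$colors[eb, , drop = FALSE]) / 2
    colors <- rbind(mesh$colors, round(ec))
  }
  triangle_mesh(rbind(vnew, emid), faces_new, colors)
}
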