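#' Build the specimen-by-coordinate shape table
#'
#' Flattens each homologous model into one row of interleaved vertex
#' coordinates `(x1, y1, z1, x2, ...)` in the head frame, giving an
#' N x 3V matrix (a 17,709-vertex model yields a 53,127-column row).
#' All models must share the template topology. With `normalize_by_cs`,
#' each row is divided by that specimen's centroid size, giving unitless
#' shape rows (each row then has centroid size 1).
#'
#' @param models list of `homologous_model`s (or of [triangle_mesh()]es
#'   sharing a topology).
#' @param normalize_by_cs divide each row by its centroid size.
#' @param groups optional character vector of group labels (one per model);
#'   taken from names otherwise.
#' @return an object of class `shape_table`: the numeric matrix with
#'   attributes `specimen_id`, `group`, `centroid_size` (always the sizes of
#'   the models as given, mm), `normalized`, `faces`, `n_vertex`.
#' @export
build_shape_table <- function(models, normalize_by_cs = FALSE, groups = NULL) {
  if (length(models) == 0L) stop("no models")
  meshes <- lapply(models, function(m)
    if (inherits(m, "homologous_model")) m$mesh else m)
  keys <- vapply(meshes, .topology_key, "")
  if (length(unique(keys)) != 1L)
    stop("models do not share one topology")
  ids <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (inherits(m, "homologous_model") && !is.null(m$id)) m$id
    else names(models)[i] %||% sprintf("S%03d", i)
  }, "")
  cs <- vapply(meshes, centroid_size, 0)
  rows <- t(vapply(meshes, function(m) as.vector(t(m$vertices)),
                   numeric(3L * n_vertices(meshes[[1]]))))
  if (normalize_by_cs) rows <- rows / cs
  rownames(rows) <- ids
  structure(rows,
            specimen_id = ids,
            group = groups %||% rep(NA_character_, length(models)),
            centroid_size = cs,
            normalized = isTRUE(normalize_by_cs),
            faces = meshes[[1]]$faces,
            n_vertex = n_vertices(meshes[[1]]),
            class = c("shape_table", "matrix"))
}

#' Principal component analysis of a shape table
#'
#' Covariance PCA (no per-coordinate standardisation; coordinates share mm
#' units) of the mean-centred rows, computed through the N x N Gram (dual)
#' eigendecomposition since the coordinate dimension vastly exceeds the
#' specimen count. Sample covariance uses the N-1 convention, so the score
#' SD of component k equals `sqrt(eigenvalue_k)`. Each component's sign is
#' fixed so that its largest-|loading| coordinate loads positively, making
#' orientations reproducible.
#'
#' @param table a [build_shape_table()] result.
#' @param tol relative eigenvalue cutoff below which components are dropped.
#' @return an object of class `shape_space`: list with `mean` (3V),
#'   `eigenvalues`, `contribution` (%), `cumulative` (%), `components`
#'   (3V x K, unit columns), `scores` (N x K), `sdev`, plus the table's
#'   bookkeeping attributes (`faces`, `n_vertex`, `specimen_id`, `group`,
#'   `centroid_size`, `normalized`).
#' @export
fit_shape_pca <- function(table, tol = 1e-10) {
  stopifnot(inherits(table, "shape_table"))
  X <- unclass(table)
  n <- nrow(X)
  if (n < 3L) stop("PCA needs at least 3 specimens")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  G <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  total <- sum(pmax(lam, 0))
  if (total <= 0) stop("zero-variance shape table")
  keep <- which(lam > tol * lam[1])
  lam <- lam[keep]
  U <- eg$vectors[, keep, drop = FALSE]
  # component vectors: W = Xc' U / (singular value); unit columns
  d <- sqrt(lam * (n - 1))
  W <- crossprod(Xc, U) / rep(d, each = ncol(Xc))
  scores <- U * rep(d, each = n)

  # sign convention via the largest-|loading| coordinate
  col_sd <- sqrt(pmax(colSums(Xc^2) / (n - 1), 0))
  num <- crossprod(Xc, scores) / (n - 1)                 # cov(coord, score)
  for (k in seq_along(lam)) {
    load_k <- num[, k] / (col_sd * sqrt(lam[k]))
    load_k[!is.finite(load_k)] <- 0
    s <- sign(load_k[which.max(abs(load_k))])
    if (s < 0) {
      W[, k] <- -W[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_along(lam))
  structure(list(mean = mu, eigenvalues = lam,
                 contribution = 100 * lam / total,
                 cumulative = cumsum(100 * lam / total),
                 components = W, scores = scores, sdev = sqrt(lam),
                 n = n,
                 specimen_id = attr(table, "specimen_id"),
                 group = attr(table, "group"),
                 centroid_size = attr(table, "centroid_size"),
                 normalized = attr(table, "normalized"),
                 faces = attr(table, "faces"),
                 n_vertex = attr(table, "n_vertex")),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d specimens, %d components (%s data)\n",
              x$n, length(x$eigenvalues),
              if (isTRUE(x$normalized)) "normalized" else "non-normalized"))
  print(utils::head(tidy(x), 5))
  invisible(x)
}

#' Components above a contribution threshold
#'
#' @param space a [fit_shape_pca()] result.
#' @param threshold_pct contribution-rate threshold in percent (e.g. 1 for
#'   the reporting set, 2 for the discrimination set).
#' @return integer vector of component ids, in order.
#' @export
select_components <- function(space, threshold_pct) {
  which(space$contribution > threshold_pct)
}

#' Per-coordinate loadings of a component
#'
#' The loading of each coordinate is the Pearson correlation between that
#' coordinate column and the component's scores (always in \[-1, 1\];
#' zero-variance coordinates load 0 by convention). Raw eigenvector entries
#' are available via `type = "eigenvector"`.
#'
#' @param space a [fit_shape_pca()] result.
#' @param table the [build_shape_table()] the space was fitted to.
#' @param comp component id.
#' @param type `"correlation"` (default) or `"eigenvector"`.
#' @return numeric vector of length 3V, interleaved like the table columns.
#' @export
vertex_loadings <- function(space, table, comp, type = "correlation") {
  stopifnot(comp %in% seq_along(space$eigenvalues))
  type <- match.arg(type, c("correlation", "eigenvector"))
  if (type == "eigenvector") return(space$components[, comp])
  X <- unclass(table)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  sc <- space$scores[, comp]
  num <- as.vector(crossprod(Xc, sc - mean(sc))) / (n - 1)
  den <- sqrt(pmax(colSums(Xc^2) / (n - 1), 0)) * stats::sd(sc)
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, -1), 1)
}

.color_classes <- c(uncolored = "uncolored", X = "red", Y = "green",
                    Z = "dark_blue", YZ = "light_blue", XZ = "pink",
                    XY = "yellow", XYZ = "white")

#' Per-vertex colour classification of high-loading zones
#'
#' For each vertex, the set of coordinate axes whose |loading| on the
#' component exceeds the threshold determines the colour class:
#' X only = red, Y only = green, Z only = dark blue, Y+Z = light blue,
#' X+Z = pink, X+Y = yellow, all three = white, none = uncolored.
#'
#' @param space,table,comp as in [vertex_loadings()].
#' @param threshold loading threshold in (0, 1) (0.45, 0.40 and 0.30 are
#'   the conventional choices for progressively later components).
#' @return tibble with `vertex`, per-axis loadings, `class` (factor) and
#'   `rgb` (hex colour; NA for uncolored).
#' @export
color_map <- function(space, table, comp, threshold = 0.45) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  ld <- vertex_loadings(space, table, comp)
  V <- space$n_vertex
  lx <- ld[seq(1, 3 * V, by = 3)]
  ly <- ld[seq(2, 3 * V, by = 3)]
  lz <- ld[seq(3, 3 * V, by = 3)]
  hx <- abs(lx) > threshold
  hy <- abs(ly) > threshold
  hz <- abs(lz) > threshold
  key <- paste0(ifelse(hx, "X", ""), ifelse(hy, "Y", ""), ifelse(hz, "Z", ""))
  key[key == ""] <- "uncolored"
  cls <- factor(.color_classes[key], levels = unname(.color_classes))
  rgbs <- c(uncolored = NA, red = "#FF0000", green = "#00B000",
            dark_blue = "#00008B", light_blue = "#66CCFF", pink = "#FF88BB",
            yellow = "#FFFF00", white = "#FFFFFF")
  tibble::tibble(vertex = seq_len(V), loading_x = lx, loading_y = ly,
                 loading_z = lz, class = cls, rgb = unname(rgbs[as.character(cls)]))
}

#' Paint a colour map onto the mean mesh
#'
#' @param space a [fit_shape_pca()] result.
#' @param cmap a [color_map()] tibble.
#' @return the mean-shape [triangle_mesh()] with per-vertex RGB colours
#'   (uncolored vertices are light grey), ready for PLY export.
#' @export
color_map_mesh <- function(space, cmap) {
  mesh <- virtual_shape(space, comp = 1L, k_sd = 0)
  hex <- ifelse(is.na(cmap$rgb), "#C8C8C8", cmap$rgb)
  cols <- t(grDevices::col2rgb(hex))
  triangle_mesh(mesh$vertices, mesh$faces, cols)
}

#' Virtual shape along a component axis
#'
#' The mesh at `mean + k_sd * sqrt(eigenvalue) * component`, i.e. the shape
#' `k_sd` standard deviations from the mean along one component (the
#' conventional displays sit at +/- 3 SD). `k_sd = 0` returns the mean
#' shape exactly.
#'
#' @param space a [fit_shape_pca()] result.
#' @param comp component id.
#' @param k_sd signed offset in score standard deviations.
#' @return a [triangle_mesh()] with the homologous topology.
#' @export
virtual_shape <- function(space, comp, k_sd) {
  stopifnot(comp %in% seq_along(space$eigenvalues))
  v <- space$mean + k_sd * space$sdev[comp] * space$components[, comp]
  triangle_mesh(matrix(v, ncol = 3, byrow = TRUE), space$faces)
}

#' Project flattened shapes onto a component
#'
#' @param space a [fit_shape_pca()] result.
#' @param mesh a [triangle_mesh()] with the homologous topology (or a
#'   numeric vector of length 3V).
#' @param comp component id.
#' @return the score (same units as `space$scores`).
#' @export
project_shape <- function(space, mesh, comp) {
  v <- if (inherits(mesh, "triangle_mesh")) as.vector(t(mesh$vertices))
       else as.numeric(mesh)
  sum((v - space$mean) * space$components[, comp])
}

#' Vertex-wise average of homologous models
#'
#' @param models non-empty list of `homologous_model`s or meshes sharing a
#'   topology.
#' @return the average [triangle_mesh()].
#' @export
group_average_model <- function(models) {
  if (length(models) == 0L) stop("empty model subset")
  meshes <- lapply(models, function(m)
    if (inherits(m, "homologous_model")) m$mesh else m)
  keys <- vapply(meshes, .topology_key, "")
  if (length(unique(keys)) != 1L) stop("models do not share one topology")
  v <- Reduce(`+`, lapply(meshes, `[[`, "vertices")) / length(meshes)
  triangle_mesh(v, meshes[[1]]$faces)
}

#' Morph sequence along a component axis
#'
#' Evenly spaced virtual shapes across `k_range`; the endpoints equal
#' [virtual_shape()] at the range ends.
#'
#' @param space a [fit_shape_pca()] result.
#' @param comp component id.
#' @param k_range length-2 numeric, SD offsets of the first and last frame.
#' @param steps number of frames (>= 2).
#' @return list of [triangle_mesh()]es.
#' @export
morph_sequence <- function(space, comp, k_range = c(-3, 3), steps = 7) {
  if (steps < 2) stop("steps must be >= 2")
  ks <- seq(k_range[1], k_range[2], length.out = steps)
  lapply(ks, function(k) virtual_shape(space, comp, k))
}

#' Tidy PCA summaries
#'
#' `tidy()` returns the component table (eigenvalue, contribution %,
#' cumulative %); `glance()` a one-row summary.
#'
#' @param x a `shape_space`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.shape_space <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 contribution_pct = x$contribution,
                 cumulative_pct = x$cumulative)
}

#' @rdname tidy.shape_space
#' @export
glance.shape_space <- function(x, ...) {
  tibble::tibble(n_specimens = x$n,
                 n_components = length(x$eigenvalues),
                 n_over_1pct = length(select_components(x, 1)),
                 n_over_2pct = length(select_components(x, 2)),
                 total_variance = sum(x$eigenvalues),
                 normalized = isTRUE(x$normalized))
}

#' Scree / contribution plot of a shape space
#' @param object a `shape_space`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.shape_space <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$contribution_pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = c(1, 2), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "principal component", y = "contribution rate (%)") +
    ggplot2::theme_minimal()
}
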