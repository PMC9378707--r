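## Synthetic cranial anatomy
##
## All specimens are images of one smooth parameterized base surface: an
## ellipsoidal neurocranium (semi-axes 70 x 65 x 85 mm) with a facial block
## and a pair of zygomatic ridges added as smooth radial bumps, the cranial
## base removed below a polar-angle cutoff (leaving one boundary loop).
## Parameters are spherical: theta is the polar angle from the vault apex
## (+y), phi the azimuth with phi = 0 facing forward (+z) and phi > 0 on the
## anatomical right (+x). Shape modes and landmarks are analytic functions
## of (theta, phi), so ground truth is exact.

.sph_dir <- function(theta, phi) {
  cbind(sin(theta) * sin(phi), cos(theta), sin(theta) * cos(phi))
}

.wrap_pi <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

# neutral radius (mm) of the cranial base surface
.cranial_radius <- function(theta, phi) {
  d <- .sph_dir(theta, phi)
  re <- 1 / sqrt((d[, 1] / 70)^2 + (d[, 2] / 65)^2 + (d[, 3] / 85)^2)
  w <- .wrap_pi(phi)
  face <- 22 * exp(-((theta - 1.90)^2 / (2 * 0.45^2) + w^2 / (2 * 0.50^2)))
  zyg <- 7 * (exp(-((theta - 1.75)^2 / (2 * 0.25^2) +
                      (w - 0.95)^2 / (2 * 0.28^2))) +
              exp(-((theta - 1.75)^2 / (2 * 0.25^2) +
                      (w + 0.95)^2 / (2 * 0.28^2))))
  re + face + zyg
}

# smooth facial mask in [0, 1] used by the projection / height modes
.face_mask <- function(theta, phi) {
  w <- .wrap_pi(phi)
  exp(-((theta - 2.00)^2 / (2 * 0.50^2) + w^2 / (2 * 0.60^2)))
}

# full specimen map: parameters -> mm coordinates
# coef: list(size = mode-1 scale s, c2 = length/breadth, c3 = facial
# projection, c4 = facial height); noise: list(centers K x 3, sigma, amp);
# rigid: list(R, t)
.specimen_points <- function(theta, phi, coef = NULL, noise = NULL,
                             rigid = NULL) {
  if (is.null(coef)) coef <- list(size = 1, c2 = 0, c3 = 0, c4 = 0)
  d <- .sph_dir(theta, phi)
  p <- .cranial_radius(theta, phi) * d
  if (coef$c2 != 0) {
    p[, 1] <- p[, 1] * (1 + coef$c2)
    p[, 3] <- p[, 3] * (1 - coef$c2)
  }
  if (coef$c3 != 0 || coef$c4 != 0) {
    m <- .face_mask(theta, phi)
    p[, 3] <- p[, 3] + 10 * coef$c3 * m
    p[, 2] <- p[, 2] - 10 * coef$c4 * m
  }
  p <- p * coef$size
  if (!is.null(noise) && length(noise$amp) > 0) {
    ca <- pmin(pmax(d %*% t(noise$centers), -1), 1)
    ang <- acos(ca)
    bump <- exp(-sweep(ang^2, 2, 2 * noise$sigma^2, "/")) %*% noise$amp
    p <- p + as.vector(bump) * d
  }
  if (!is.null(rigid)) p <- p %*% t(rigid$R) + rep(rigid$t, each = nrow(p))
  p
}

# UV grid over the parameter domain: apex vertex + n_theta rings of M
.grid_params <- function(M, n_theta, theta_max, phi0 = 0) {
  theta <- c(0, rep(seq_len(n_theta) * theta_max / n_theta, each = M))
  phi <- c(0, rep((seq_len(M) - 1) * 2 * pi / M + phi0, n_theta))
  faces <- matrix(0L, 0L, 3L)
  vid <- function(i, j) 1L + (i - 1L) * M + ((j - 1L) %% M) + 1L
  j <- seq_len(M)
  fan <- cbind(1L, vid(1L, j + 1L), vid(1L, j))
  quads <- NULL
  if (n_theta > 1L) {
    i <- rep(seq_len(n_theta - 1L), each = M)
    jj <- rep(j, n_theta - 1L)
    quads <- rbind(cbind(vid(i, jj), vid(i, jj + 1L), vid(i + 1L, jj + 1L)),
                   cbind(vid(i, jj), vid(i + 1L, jj + 1L), vid(i + 1L, jj)))
  }
  list(theta = theta, phi = phi, faces = rbind(fan, quads),
       M = M, n_theta = n_theta, theta_max = theta_max)
}

# orient faces so normals point away from the centroid
.orient_outward <- function(verts, faces) {
  m <- triangle_mesh(verts, faces)
  fn <- face_normals(m)
  ctr <- colMeans(verts)
  fc <- (verts[faces[, 1], ] + verts[faces[, 2], ] + verts[faces[, 3], ]) / 3
  if (mean(rowSums(fn * sweep(fc, 2, ctr))) < 0)
    faces <- faces[, c(1L, 3L, 2L)]
  faces
}

# canonical landmark parameters (degrees); right side phi > 0
.landmark_params_deg <- function() {
  mid <- rbind(
    nasion = c(88, 0), glabella = c(78, 0), bregma = c(25, 0),
    vertex_point = c(5, 0), obelion = c(25, 180), lambda = c(45, 180),
    opisthocranion = c(85, 180), inion = c(105, 180),
    opisthion_region = c(135, 180), basion_region = c(142, 180),
    subspinale_region = c(118, 0), rhinion = c(100, 0))
  bil <- rbind(
    porion = c(92, 90), orbitale = c(106, 25), zygion = c(98, 55),
    frontomalare = c(88, 38), euryon = c(65, 95), asterion = c(110, 140),
    mastoidale = c(125, 105), frontotemporale = c(62, 40),
    dacryon = c(92, 14), ectoconchion = c(94, 32), zygomaxillare = c(110, 35),
    alare = c(108, 10), jugale = c(96, 48), stephanion = c(45, 45),
    pterion = c(75, 60), auriculare = c(88, 82), krotaphion = c(80, 70),
    zygoorbitale = c(102, 28), supraorbital_point = c(82, 20),
    infraorbital_point = c(104, 18), sphenion = c(78, 52), coronale = c(35, 60))
  list(mid = mid, bil = bil)
}

# snap landmark parameters to grid nodes of an (M, n_theta, theta_max) grid,
# resolving collisions deterministically and mirroring right -> left exactly
.snapped_landmarks <- function(M, n_theta, theta_max) {
  lp <- .landmark_params_deg()
  dth <- theta_max / n_theta
  dph <- 2 * pi / M
  used <- character(0)
  place <- function(i, j) {
    i <- min(max(i, 1L), n_theta)
    j <- ((j - 1L) %% M) + 1L
    c(i, j)
  }
  out <- list()
  # midline: j fixed at phi = 0 (j = 1) or phi = pi (j = M/2 + 1)
  for (nm in rownames(lp$mid)) {
    th <- lp$mid[nm, 1] * pi / 180
    j <- if (lp$mid[nm, 2] == 0) 1L else M %/% 2L + 1L
    i <- as.integer(round(th / dth))
    repeat {
      ij <- place(i, j)
      key <- paste(ij, collapse = ",")
      if (!key %in% used) break
      i <- i + 1L
    }
    used <- c(used, key)
    out[[nm]] <- ij
  }
  # bilateral: snap the right side, then mirror
  for (nm in rownames(lp$bil)) {
    th <- lp$bil[nm, 1] * pi / 180
    ph <- lp$bil[nm, 2] * pi / 180
    i <- as.integer(round(th / dth))
    j <- as.integer(round(ph / dph)) + 1L
    tries <- 0L
    repeat {
      ij <- place(i, j)
      jm <- ((M - (ij[2] - 1L)) %% M) + 1L
      keyr <- paste(ij, collapse = ",")
      keyl <- paste(c(ij[1], jm), collapse = ",")
      if (!keyr %in% used && !keyl %in% used && keyr != keyl) break
      tries <- tries + 1L
      if (tries %% 2L == 1L) j <- j + (tries + 1L) %/% 2L
      else i <- i + tries %/% 2L
    }
    used <- c(used, keyr, keyl)
    out[[paste0(nm, "_r")]] <- ij
    out[[paste0(nm, "_l")]] <- c(ij[1], jm)
  }
  nodes <- do.call(rbind, out)
  tibble::tibble(
    name = rownames(nodes),
    theta = nodes[, 1] * dth,
    phi = (nodes[, 2] - 1) * dph,
    vertex = 1L + (nodes[, 1] - 1L) * M + (nodes[, 2] - 1L) + 1L)
}

#' Build the symmetric cranial template mesh with its 56 landmarks
#'
#' Constructs the smooth cranium-like template surface (ellipsoidal vault,
#' facial block, zygomatic ridges; cranial base removed, leaving a single
#' boundary loop), exactly bilaterally symmetric about the x = 0 midsagittal
#' plane, with the 56 canonical landmarks bound to distinct vertices.
#'
#' @param resolution target vertex count (default 4500; the realized count
#'   depends on the grid and lands in roughly 0.9--1.1 x the target).
#' @return an object of class `cranial_template`: a list with `mesh`
#'   ([triangle_mesh()]), `landmarks` ([landmark_set()] at the bound
#'   vertices), `lm_vertices` (named vertex indices), `mirror_pairs`
#'   (involution for [symmetrize()]), `schema` (tibble of snapped landmark
#'   parameters) and `grid` (grid bookkeeping).
#' @export
make_template <- function(resolution = 4500) {
  theta_max <- 2.60
  M <- 2L * as.integer(round(sqrt(2 * pi / theta_max * (resolution - 1)) / 2))
  n_theta <- as.integer(round((resolution - 1) / M))
  g <- .grid_params(M, n_theta, theta_max)
  verts <- .specimen_points(g$theta, g$phi)
  faces <- .orient_outward(verts, g$faces)
  mesh <- triangle_mesh(verts, faces)

  # mirror pairing (i, j) <-> (i, M - j + 2); apex and midline self-paired
  nv <- nrow(verts)
  idx <- seq(2L, nv)
  gi <- (idx - 2L) %/% M + 1L
  gj <- (idx - 2L) %% M + 1L
  pairs <- c(1L, 1L + (gi - 1L) * M + ((M - (gj - 1L)) %% M) + 1L)
  schema <- .snapped_landmarks(M, n_theta, theta_max)
  lmv <- stats::setNames(schema$vertex, schema$name)
  lms <- landmark_set(verts[lmv, , drop = FALSE], names = schema$name)
  structure(list(mesh = mesh, landmarks = lms, lm_vertices = lmv,
                 mirror_pairs = pairs, schema = schema,
                 grid = g[c("M", "n_theta", "theta_max")]),
            class = "cranial_template")
}

#' @export
print.cranial_template <- function(x, ...) {
  cat(sprintf("<cranial_template> %d vertices, %d faces, %d landmarks\n",
              n_vertices(x$mesh), n_faces(x$mesh), nrow(x$schema)))
  invisible(x)
}

#' Specification of a synthetic cranial population
#'
#' Defines the ground-truth population structure from which
#' [sample_population()] draws: per-group mean offsets on the four shape
#' modes, within-group spread, overall size distribution, smooth surface
#' noise, and scan resolution. Mode 1 is overall (isotropic) size, mode 2
#' the vault length/breadth proportion, mode 3 facial forward projection,
#' mode 4 facial height.
#'
#' @param n_groups number of groups (>= 1).
#' @param n_per_group specimens per group.
#' @param group_offsets numeric matrix `n_groups` x 4 with columns
#'   `size_mm` (added to `size_mean`), `mode2`, `mode3`, `mode4`. Default:
#'   each group is offset on its "own" mode (size, then modes 2..4, cycling).
#' @param mode_sd within-group SDs of modes 2..4 (unitless coefficients).
#' @param size_mean,size_sd overall cranial length scale in mm (mode-1
#'   coefficient is `size/size_mean`, i.e. the template sits at 1).
#' @param noise_sd SD (mm) of the amplitudes of the smooth per-specimen
#'   surface perturbation bumps; 0 disables noise.
#' @param resolution target vertex count of each generated scan.
#' @param template_resolution resolution of the template whose snapped
#'   landmark schema the scans share.
#' @param landmark_noise_sd isotropic Gaussian SD (mm) emulating manual
#'   landmark placement error (default 0: analytic placement).
#' @param allometry_b if nonzero, the mode given by `allometry_mode` gains a
#'   deterministic `b * log(size / size_mean)` term, injecting a power-law
#'   size--shape link with known coefficient sign.
#' @param allometry_mode which mode (2--4) carries the allometric link.
#' @param rigid_jitter apply a random rigid motion to each scan (default
#'   TRUE; disable to keep scans in the canonical anatomical frame).
#' @param seed integer seed; fully determines all outputs.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_groups = 4, n_per_group = 15,
                            group_offsets = NULL,
                            mode_sd = c(mode2 = 0.03, mode3 = 0.3, mode4 = 0.3),
                            size_mean = 170, size_sd = 6,
                            noise_sd = 0.3, resolution = 20000,
                            template_resolution = 4500,
                            landmark_noise_sd = 0,
                            allometry_b = 0, allometry_mode = 4L,
                            rigid_jitter = TRUE, seed = 1L) {
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (any(c(mode_sd, size_sd, noise_sd, landmark_noise_sd) < 0))
    stop("all SDs must be >= 0")
  if (is.null(group_offsets)) {
    base <- rbind(c(8, 0, 0, 0), c(0, 0.06, 0, 0),
                  c(0, 0, 0.6, 0), c(0, 0, 0, 0.6))
    group_offsets <- base[((seq_len(n_groups) - 1L) %% 4L) + 1L, , drop = FALSE]
    if (n_groups == 1) group_offsets[] <- 0
  }
  group_offsets <- as.matrix(group_offsets)
  if (nrow(group_offsets) != n_groups || ncol(group_offsets) != 4L)
    stop("group_offsets must be an n_groups x 4 matrix")
  colnames(group_offsets) <- c("size_mm", "mode2", "mode3", "mode4")
  structure(list(n_groups = as.integer(n_groups),
                 n_per_group = as.integer(n_per_group),
                 group_offsets = group_offsets,
                 mode_sd = stats::setNames(as.numeric(mode_sd),
                                           c("mode2", "mode3", "mode4")),
                 size_mean = size_mean, size_sd = size_sd,
                 noise_sd = noise_sd, resolution = as.integer(resolution),
                 template_resolution = as.integer(template_resolution),
                 landmark_noise_sd = landmark_noise_sd,
                 allometry_b = allometry_b,
                 allometry_mode = as.integer(allometry_mode),
                 rigid_jitter = isTRUE(rigid_jitter),
                 seed = as.integer(seed)),
            class = "population_spec")
}

# uniform random rotation (det +1)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

#' Sample a synthetic scan population with ground truth
#'
#' Draws `n_groups * n_per_group` specimens from the generative model in
#' `spec`: per-specimen mode coefficients (group mean + individual draw),
#' smooth surface noise, an individual re-triangulation (every scan has its
#' own vertex count and connectivity, distinct from the template), analytic
#' landmarks transformed with the deformation, and (by default) a random
#' rigid pose.
#'
#' @param spec a [population_spec()].
#' @return a list with `scans` (list of [triangle_mesh()]), `landmarks`
#'   (list of [landmark_set()]), and `truth`, a tibble with one row per
#'   specimen: `specimen_id`, `group`, the mode coefficients `size` (mode 1,
#'   template = 1), `mode2`..`mode4`, and `size_mm`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_groups * spec$n_per_group
  group <- rep(paste0("G", seq_len(spec$n_groups)), each = spec$n_per_group)
  schema <- .snapped_landmarks_for(spec)

  size_mm <- spec$size_mean + spec$group_offsets[match(group, unique(group)),
                                                 "size_mm"] +
    rnorm(n, 0, spec$size_sd)
  s <- size_mm / spec$size_mean
  gidx <- match(group, unique(group))
  c2 <- spec$group_offsets[gidx, "mode2"] + rnorm(n, 0, spec$mode_sd["mode2"])
  c3 <- spec$group_offsets[gidx, "mode3"] + rnorm(n, 0, spec$mode_sd["mode3"])
  c4 <- spec$group_offsets[gidx, "mode4"] + rnorm(n, 0, spec$mode_sd["mode4"])
  if (spec$allometry_b != 0) {
    extra <- spec$allometry_b * log(s)
    if (spec$allometry_mode == 2L) c2 <- c2 + extra
    else if (spec$allometry_mode == 3L) c3 <- c3 + extra
    else c4 <- c4 + extra
  }

  # distinct even ring counts give every scan its own topology
  Ms <- sample(seq(100L, 100L + 2L * max(n + 10L, 80L), by = 2L), n)
  scans <- vector("list", n)
  lms <- vector("list", n)
  for (k in seq_len(n)) {
    coef <- list(size = s[k], c2 = c2[k], c3 = c3[k], c4 = c4[k])
    noise <- NULL
    if (spec$noise_sd > 0) {
      K <- 10L
      ctr <- matrix(rnorm(3 * K), K)
      ctr <- ctr / sqrt(rowSums(ctr^2))
      noise <- list(centers = ctr, sigma = runif(K, 0.25, 0.6),
                    amp = rnorm(K, 0, spec$noise_sd))
    }
    rigid <- NULL
    if (spec$rigid_jitter)
      rigid <- list(R = .random_rotation(), t = rnorm(3, 0, 50))

    M <- Ms[k]
    n_theta <- max(3L, as.integer(round((spec$resolution - 1) / M)))
    g <- .grid_params(M, n_theta, theta_max = 2.90,
                      phi0 = runif(1, 0, 2 * pi / M))
    verts <- .specimen_points(g$theta, g$phi, coef, noise, rigid)
    faces <- .orient_outward(verts, g$faces)
    scans[[k]] <- triangle_mesh(verts, faces)

    lpts <- .specimen_points(schema$theta, schema$phi, coef, noise, rigid)
    if (spec$landmark_noise_sd > 0)
      lpts <- lpts + matrix(rnorm(length(lpts), 0, spec$landmark_noise_sd),
                            ncol = 3)
    lms[[k]] <- landmark_set(lpts, names = schema$name)
  }
  ids <- sprintf("S%03d", seq_len(n))
  truth <- tibble::tibble(specimen_id = ids, group = group,
                          size = s, mode2 = c2, mode3 = c3, mode4 = c4,
                          size_mm = size_mm)
  list(scans = stats::setNames(scans, ids),
       landmarks = stats::setNames(lms, ids),
       truth = truth)
}

# schema shared between a spec's scans and its template
.snapped_landmarks_for <- function(spec) {
  tpl <- make_template(spec$template_resolution)
  tpl$schema
}

# analytic derivative directions of each injected mode at given parameter
# locations (used for subspace-recovery diagnostics): finite differences of
# the generator map around the neutral shape
.mode_directions <- function(theta, phi, eps = 1e-4) {
  base <- .specimen_points(theta, phi)
  pert <- function(coef) {
    (.specimen_points(theta, phi, coef) - base) / eps
  }
  list(size = pert(list(size = 1 + eps, c2 = 0, c3 = 0, c4 = 0)),
       mode2 = pert(list(size = 1, c2 = eps, c3 = 0, c4 = 0)),
       mode3 = pert(list(size = 1, c2 = 0, c3 = eps, c4 = 0)),
       mode4 = pert(list(size = 1, c2 = 0, c3 = 0, c4 = eps)))
}
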