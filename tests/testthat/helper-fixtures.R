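# Fixtures are built in code; expensive shared objects are memoised for the
# duration of the test run.

.fx <- new.env(parent = emptyenv())

make_tetrahedron <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

make_single_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

# regular grid over [0,1]^2 at z = z0, (n+1)^2 vertices
make_plane_grid <- function(n = 10, z0 = 0) {
  g <- expand.grid(x = 0:n / n, y = 0:n / n)
  v <- cbind(g$x, g$y, z0)
  id <- function(i, j) i * (n + 1) + j + 1
  i <- rep(0:(n - 1), each = n); j <- rep(0:(n - 1), n)
  f <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
             cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  triangle_mesh(v, f)
}

# closed UV sphere of given radius
make_uv_sphere <- function(radius = 1, n_theta = 40, n_phi = 80) {
  th <- seq_len(n_theta - 1) * pi / n_theta
  ph <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  g <- expand.grid(ph = ph, th = th)
  v <- radius * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph),
                      cos(g$th))
  v <- rbind(c(0, 0, radius), v, c(0, 0, -radius))
  top <- 1L; bot <- nrow(v)
  id <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  j <- seq_len(n_phi)
  f <- rbind(cbind(top, id(1, j), id(1, j + 1)))
  if (n_theta > 2) {
    i <- rep(seq_len(n_theta - 2), each = n_phi)
    jj <- rep(j, n_theta - 2)
    f <- rbind(f,
               cbind(id(i, jj), id(i + 1, jj), id(i + 1, jj + 1)),
               cbind(id(i, jj), id(i + 1, jj + 1), id(i, jj + 1)))
  }
  f <- rbind(f, cbind(bot, id(n_theta - 1, j + 1), id(n_theta - 1, j)))
  triangle_mesh(v, f)
}

random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  list(R = R, t = rnorm(3, 0, 50), s = 1)
}

small_template <- function() {
  if (is.null(.fx$tpl)) .fx$tpl <- make_template(1200)
  .fx$tpl
}

# a small fitted synthetic study shared by shape-space tests
small_fitted_batch <- function() {
  if (!is.null(.fx$batch)) return(.fx$batch)
  tpl <- small_template()
  pop <- population_spec(n_groups = 2, n_per_group = 3, resolution = 5000,
                         template_resolution = 1200, seed = 11)
  dat <- sample_population(pop)
  models <- lapply(names(dat$scans), function(id)
    fit_homologous(tpl, dat$scans[[id]], scan_lms = dat$landmarks[[id]],
                   id = id))
  names(models) <- names(dat$scans)
  .fx$batch <- list(template = tpl, pop = pop, dat = dat, models = models)
  .fx$batch
}
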