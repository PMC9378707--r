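# small synthetic "homologous" meshes sharing one topology, for PCA tests
.toy_models <- function(n = 10, nv = 10, sd = 1, seed = 1) {
  set.seed(seed)
  faces <- cbind(seq_len(nv - 2), seq_len(nv - 2) + 1L, seq_len(nv - 2) + 2L)
  base <- matrix(rnorm(3 * nv, 0, 20), nv)
  lapply(seq_len(n), function(i)
    triangle_mesh(base + matrix(rnorm(3 * nv, 0, sd), nv), faces))
}

test_that("shape table rows are interleaved coordinates with 3V columns", {
  models <- .toy_models(4, nv = 7)
  tab <- build_shape_table(models)
  expect_equal(ncol(tab), 21L)
  expect_equal(tab[2, 1:6],
               c(models[[2]]$vertices[1, ], models[[2]]$vertices[2, ]),
               ignore_attr = TRUE)
  # a 17,709-vertex model yields a 53,127-column row
  big <- triangle_mesh(matrix(rnorm(3 * 17709), 17709),
                       rbind(c(1, 2, 3)))
  tab_big <- build_shape_table(list(big, big))
  expect_equal(ncol(tab_big), 53127L)
  # identical models give identical rows
  expect_equal(tab_big[1, ], tab_big[2, ], ignore_attr = TRUE)
  expect_error(build_shape_table(list(models[[1]], make_tetrahedron())),
               "topology")
})

test_that("centroid-size normalisation yields unit-size rows", {
  models <- .toy_models(3, nv = 12)
  tab <- build_shape_table(models, normalize_by_cs = TRUE)
  for (i in 1:3) {
    row_mesh <- matrix(tab[i, ], ncol = 3, byrow = TRUE)
    expect_equal(centroid_size(row_mesh), 1, tolerance = 1e-12)
  }
  # the recorded centroid sizes stay those of the models in mm
  expect_equal(attr(tab, "centroid_size"),
               vapply(models, centroid_size, 0), tolerance = 1e-12)
})

test_that("dual-form PCA matches the direct covariance eigendecomposition", {
  models <- .toy_models(10, nv = 10, sd = 3, seed = 4)
  tab <- build_shape_table(models)
  sp <- fit_shape_pca(tab)
  X <- unclass(tab)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  k <- length(sp$eigenvalues)
  expect_equal(sp$eigenvalues, ev[seq_len(k)], tolerance = 1e-9)
  # trace conservation
  expect_equal(sum(sp$eigenvalues), sum(diag(stats::cov(X))),
               tolerance = 1e-9)
  # contributions sum to 100
  expect_equal(sum(sp$contribution), 100, tolerance = 1e-9)
  # reconstruction of the centred table
  Xc <- sweep(X, 2, colMeans(X))
  rec <- sp$scores %*% t(sp$components)
  expect_lt(max(abs(rec - Xc)) / max(abs(Xc)), 1e-6)
  # score columns: zero mean, SD = sqrt(eigenvalue)
  expect_lt(max(abs(colMeans(sp$scores))), 1e-9)
  expect_equal(apply(sp$scores, 2, sd), sp$sdev, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two mirrored specimens give one component with known eigenvalue", {
  faces <- rbind(c(1, 2, 3))
  base <- matrix(rnorm(9, 0, 10), 3)
  delta <- matrix(rnorm(9), 3)
  # N = 3 with one specimen at the mean keeps the two-point geometry testable
  models <- list(triangle_mesh(base + delta, faces),
                 triangle_mesh(base - delta, faces),
                 triangle_mesh(base, faces))
  sp <- fit_shape_pca(build_shape_table(models))
  # single direction of variation: lambda = |delta|^2 * 2 / (N - 1)
  expect_equal(length(sp$eigenvalues), 1L)
  expect_equal(sp$eigenvalues[1], sum(delta^2) * 2 / 2, tolerance = 1e-9)
  expect_equal(sp$contribution[1], 100, tolerance = 1e-9)
})

test_that("component selection thresholds contribution rates", {
  models <- .toy_models(8, nv = 9, sd = 2, seed = 6)
  sp <- fit_shape_pca(build_shape_table(models))
  expect_identical(select_components(sp, 100), integer(0))
  ids <- select_components(sp, 1)
  expect_true(all(sp$contribution[ids] > 1))
  expect_true(all(sp$contribution[-ids] <= 1))
  # a single-component space at threshold 1 selects component 1
  faces <- rbind(c(1, 2, 3))
  base <- matrix(rnorm(9, 0, 5), 3); d <- matrix(rnorm(9), 3)
  one <- fit_shape_pca(build_shape_table(list(
    triangle_mesh(base + d, faces), triangle_mesh(base - d, faces),
    triangle_mesh(base, faces))))
  expect_identical(select_components(one, 1), 1L)
})

test_that("loadings are correlations bounded in [-1, 1]", {
  set.seed(9)
  models <- .toy_models(20, nv = 8, sd = 2, seed = 9)
  tab <- build_shape_table(models)
  sp <- fit_shape_pca(tab)
  ld <- vertex_loadings(sp, tab, 1)
  expect_true(all(ld >= -1 & ld <= 1))
  # when a single coordinate carries all the variation, the PC1 score IS
  # that coordinate (centred), so its loading is exactly 1 and all
  # zero-variance coordinates load 0 by convention
  faces1 <- rbind(c(1, 2, 3))
  basev <- matrix(rnorm(9, 0, 10), 3)
  single <- lapply(rnorm(12, 0, 4), function(t) {
    v <- basev; v[2, 2] <- v[2, 2] + t
    triangle_mesh(v, faces1)
  })
  tab2 <- build_shape_table(single)
  sp2 <- fit_shape_pca(tab2)
  ld2 <- vertex_loadings(sp2, tab2, 1)
  expect_equal(ld2[5], 1, tolerance = 1e-9)   # coord 5 = vertex 2, y
  expect_equal(ld2[-5], rep(0, 8), tolerance = 1e-12)
  # an independent-noise coordinate decouples from a strong common mode
  set.seed(10)
  faces <- rbind(c(1, 2, 3), c(2, 3, 4))
  base <- matrix(rnorm(12, 0, 10), 4)
  dir <- matrix(rnorm(12), 4); dir <- dir / sqrt(sum(dir^2))
  big <- lapply(1:80, function(i) {
    v <- base + rnorm(1, 0, 5) * dir + matrix(rnorm(12, 0, 0.01), 4)
    v[1, 1] <- rnorm(1, 0, 1)            # pure noise, independent of the mode
    triangle_mesh(v, faces)
  })
  tab3 <- build_shape_table(big)
  sp3 <- fit_shape_pca(tab3)
  expect_lt(abs(vertex_loadings(sp3, tab3, 1)[1]), 0.35)
})

test_that("color map classifies axis sets by the published palette", {
  # build loadings directly through a crafted table: vertex 1 moves with the
  # score in x only, vertex 2 in y and z, vertex 3 not at all
  set.seed(12)
  faces <- rbind(c(1, 2, 3))
  n <- 30
  sc <- rnorm(n, 0, 3)
  models <- lapply(seq_len(n), function(i) {
    v <- rbind(c(10 + sc[i], 0, 0),
               c(0, 5 + sc[i], -2 + sc[i]),
               c(3, 4, 5))
    triangle_mesh(v + matrix(rnorm(9, 0, 1e-3), 3), faces)
  })
  tab <- build_shape_table(models)
  sp <- fit_shape_pca(tab)
  cm <- color_map(sp, tab, 1, threshold = 0.45)
  expect_equal(as.character(cm$class[1]), "red")
  expect_equal(as.character(cm$class[2]), "light_blue")
  expect_equal(as.character(cm$class[3]), "uncolored")
  expect_true(is.na(cm$rgb[3]))
  expect_error(color_map(sp, tab, 1, threshold = 1.2), "threshold")
  # painted mesh is exportable with colors
  pm <- color_map_mesh(sp, cm)
  expect_false(is.null(pm$colors))
})

test_that("virtual shapes sit exactly k SD along their component", {
  models <- .toy_models(12, nv = 10, sd = 2, seed = 14)
  tab <- build_shape_table(models)
  sp <- fit_shape_pca(tab)
  m0 <- virtual_shape(sp, 1, 0)
  expect_equal(as.vector(t(m0$vertices)), sp$mean, tolerance = 1e-12)
  vp <- virtual_shape(sp, 2, 3)
  expect_equal(project_shape(sp, vp, 2), 3 * sp$sdev[2],
               tolerance = 1e-9 * sp$sdev[2])
  # +k and -k are mirror images about the mean
  vm <- virtual_shape(sp, 2, -3)
  mid <- (as.vector(t(vp$vertices)) + as.vector(t(vm$vertices))) / 2
  expect_equal(mid, sp$mean, tolerance = 1e-9)
})

test_that("group averages and morph sequences are linear in the models", {
  models <- .toy_models(5, nv = 6, sd = 1, seed = 15)
  expect_equal(group_average_model(models[1])$vertices,
               models[[1]]$vertices)
  shifted <- triangle_mesh(models[[1]]$vertices + 2, models[[1]]$faces)
  avg <- group_average_model(list(models[[1]], shifted))
  expect_equal(avg$vertices, models[[1]]$vertices + 1, tolerance = 1e-12)
  expect_error(group_average_model(list()), "empty")

  tab <- build_shape_table(models)
  sp <- fit_shape_pca(tab)
  # the average's score equals the mean of member scores
  sub <- models[2:4]
  avg2 <- group_average_model(sub)
  expect_equal(project_shape(sp, avg2, 1), mean(sp$scores[2:4, 1]),
               tolerance = 1e-9)

  seqs <- morph_sequence(sp, 1, c(-2, 2), steps = 5)
  expect_equal(length(seqs), 5L)
  expect_equal(seqs[[1]]$vertices, virtual_shape(sp, 1, -2)$vertices)
  expect_equal(seqs[[5]]$vertices, virtual_shape(sp, 1, 2)$vertices)
  expect_equal(seqs[[3]]$vertices, virtual_shape(sp, 1, 0)$vertices,
               tolerance = 1e-12)
  two <- morph_sequence(sp, 1, c(-3, 3), steps = 2)
  expect_equal(two[[2]]$vertices, virtual_shape(sp, 1, 3)$vertices)
  expect_error(morph_sequence(sp, 1, c(-3, 3), steps = 1), "steps")
})

test_that("tidy and glance summarise a shape space", {
  models <- .toy_models(6, nv = 6, sd = 1, seed = 16)
  sp <- fit_shape_pca(build_shape_table(models))
  td <- tidy(sp)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("component", "eigenvalue", "contribution_pct",
                     "cumulative_pct"))
  gl <- glance(sp)
  expect_equal(gl$n_specimens, 6L)
  expect_s3_class(autoplot(sp), "ggplot")
})
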