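test_that("mesh construction validates faces and colors", {
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 2))), "degenerate face")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 3)),
                             colors = rbind(c(0, 0, 300), c(1, 1, 1),
                                            c(2, 2, 2))),
               "0..255")
  m <- make_tetrahedron()
  expect_equal(n_vertices(m), 4L)
  expect_equal(nrow(mesh_edges(m)), 6L)
  expect_equal(euler_characteristic(m), 2L)
  expect_true(is_edge_manifold(m))
})

test_that("mesh round trips preserve geometry across formats", {
  m <- make_tetrahedron()
  for (fmt in c("ply", "ply_ascii", "obj")) {
    p <- tempfile(fileext = if (fmt == "obj") ".obj" else ".ply")
    write_mesh(m, p, format = fmt)
    m2 <- read_mesh(p, format = fmt)
    expect_equal(m2$faces, m$faces)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  }
  # double-precision coordinates survive the binary dialect far below 1e-6
  v <- matrix(rnorm(30, 0, 100), 10)
  mm <- triangle_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6), c(8, 9, 10)))
  p <- tempfile(fileext = ".ply")
  write_mesh(mm, p)
  expect_equal(read_mesh(p)$vertices, v, tolerance = 1e-12)
})

test_that("per-vertex colors survive the PLY round trip", {
  m <- make_tetrahedron()
  m$colors <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255), c(10, 20, 30))
  for (fmt in c("ply", "ply_ascii")) {
    p <- tempfile(fileext = ".ply")
    write_mesh(m, p, format = fmt)
    expect_equal(read_mesh(p)$colors, m$colors)
  }
})

test_that("non-triangular faces are rejected with the face named", {
  p <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 1 1 0",
               "f 1 2 3", "f 1 2 3 4"), p)
  expect_error(read_mesh(p), "face 2")
  p2 <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0", "1 1 0",
               "4 0 1 2 3"), p2)
  expect_error(read_mesh(p2), "face 1")
})

test_that("Loop subdivision inserts one vertex per edge and quadruples faces", {
  tet <- make_tetrahedron()
  s <- loop_subdivide(tet)
  expect_equal(n_vertices(s), 10L)
  expect_equal(n_faces(s), 16L)
  expect_equal(euler_characteristic(s), 2L)

  tri <- make_single_triangle()
  s1 <- loop_subdivide(tri)
  expect_equal(n_vertices(s1), 6L)
  expect_equal(n_faces(s1), 4L)

  # property: V' = V + E, F' = 4F, Euler characteristic preserved
  set.seed(7)
  meshes <- c(lapply(1:4, function(i) make_plane_grid(sample(2:6, 1))),
              lapply(1:3, function(i) make_uv_sphere(1, 6 + i, 10 + i)),
              list(make_tetrahedron(), small_template()$mesh))
  for (m in meshes) {
    s <- loop_subdivide(m)
    expect_equal(n_vertices(s), n_vertices(m) + nrow(mesh_edges(m)))
    expect_equal(n_faces(s), 4L * n_faces(m))
    expect_equal(euler_characteristic(s), euler_characteristic(m))
  }
})

test_that("Loop subdivision applies the standard smooth and crease masks", {
  # boundary edge midpoint rule on a flat strip
  strip <- make_plane_grid(1)           # unit square, 4 vertices
  s <- loop_subdivide(strip)
  # boundary edge (0,0)-(1,0): new vertex must be the midpoint
  expect_true(any(apply(s$vertices, 1, function(p)
    all(abs(p - c(0.5, 0, 0)) < 1e-12))))

  # interior edge mask 3/8 ends + 1/8 wings on the tetrahedron
  tet <- make_tetrahedron()
  st <- loop_subdivide(tet)
  v <- tet$vertices
  # edge 1-2 has wings 3 and 4
  expected <- 0.375 * (v[1, ] + v[2, ]) + 0.125 * (v[3, ] + v[4, ])
  expect_true(any(apply(st$vertices, 1, function(p)
    all(abs(p - expected) < 1e-12))))

  # even-vertex rule: valence-3 beta = 3/16
  b <- 3 / 16
  expected_v1 <- (1 - 3 * b) * v[1, ] + b * (v[2, ] + v[3, ] + v[4, ])
  expect_equal(st$vertices[1, ], expected_v1, tolerance = 1e-12)
})

test_that("non-manifold edges are rejected by subdivision", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))   # edge 1-2 in three faces
  m <- triangle_mesh(v, f)
  expect_false(is_edge_manifold(m))
  expect_error(loop_subdivide(m), "non-manifold")
})

test_that("centroid size has the closed form and scales linearly", {
  cube <- triangle_mesh(as.matrix(expand.grid(c(-.5, .5), c(-.5, .5),
                                              c(-.5, .5))),
                        rbind(c(1, 2, 3)))
  expect_equal(centroid_size(cube), sqrt(6), tolerance = 1e-12)
  m <- small_template()$mesh
  for (s in c(0.5, 2, 3.7)) {
    ms <- triangle_mesh(m$vertices * s, m$faces)
    expect_equal(centroid_size(ms), s * centroid_size(m), tolerance = 1e-9)
  }
  expect_equal(centroid_size(matrix(c(1, 2, 3), 1)), 0)
})

test_that("surface distance is exact point-to-triangle, not nearest vertex", {
  m <- small_template()$mesh
  d <- surface_distance(m, m)
  expect_equal(d$mean_point_to_surface_distance, 0, tolerance = 1e-9)

  a <- make_plane_grid(6, z0 = 0.5)
  b <- make_plane_grid(2, z0 = 0)       # coarser target: projection matters
  d2 <- surface_distance(a, b)
  expect_equal(d2$mean_point_to_surface_distance, 0.5, tolerance = 1e-12)
  expect_equal(d2$max_point_to_surface_distance, 0.5, tolerance = 1e-12)

  # analytic oracle: concentric spheres differ by the radius gap
  s1 <- make_uv_sphere(1.0, 40, 80)
  s2 <- make_uv_sphere(1.1, 60, 120)
  d3 <- surface_distance(s1, s2)
  expect_equal(d3$mean_point_to_surface_distance, 0.1, tolerance = 0.02)
})

test_that("surface distance is rigid-invariant and scale-equivariant", {
  set.seed(5)
  a <- make_uv_sphere(1, 10, 16)
  b <- make_uv_sphere(1.2, 12, 20)
  d0 <- surface_distance(a, b)$mean_point_to_surface_distance
  tr <- random_rigid()
  d1 <- surface_distance(apply_transform(a, tr),
                         apply_transform(b, tr))$mean_point_to_surface_distance
  expect_equal(d1, d0, tolerance = 1e-9)
  a3 <- triangle_mesh(a$vertices * 3, a$faces)
  b3 <- triangle_mesh(b$vertices * 3, b$faces)
  expect_equal(surface_distance(a3, b3)$mean_point_to_surface_distance,
               3 * d0, tolerance = 1e-9)
})

test_that("symmetrize averages pairs and is a fixed point on symmetric meshes", {
  tpl <- small_template()
  s <- symmetrize(tpl$mesh, tpl$mirror_pairs)
  expect_lt(max(abs(s$vertices - tpl$mesh$vertices)), 1e-9)

  # pair at x = +1.0 / x = -1.2 maps to +/- 1.1
  v <- rbind(c(1.0, 0, 0), c(-1.2, 0, 0), c(0, 1, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3)))
  sm <- symmetrize(m, pairs = c(2L, 1L, 3L))
  expect_equal(sm$vertices[1, 1], 1.1)
  expect_equal(sm$vertices[2, 1], -1.1)
  expect_equal(sm$vertices[3, 1], 0)    # midline projected onto the plane

  # postcondition: reflection asymmetry is exactly zero
  refl <- sm$vertices %*% diag(c(-1, 1, 1))
  expect_equal(refl[c(2, 1, 3), ], sm$vertices, tolerance = 1e-12)
  expect_error(symmetrize(m), "pair map")
})
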