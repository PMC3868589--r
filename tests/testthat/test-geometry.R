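test_that("truncated-ellipsoid volume matches closed forms and oracles", {
  # full sphere
  r <- 17.3
  expect_equal(truncated_ellipsoid_volume(r, r, r), 4 / 3 * pi * r^3 / 1000,
               tolerance = 1e-12)
  # unit ellipsoid cut at a third: 1-D integration oracle of the cap integral
  oracle <- integrate(function(z) pi * 1^2 * (1 - z^2 / 1^2), -1, 1 / 3,
                      rel.tol = 1e-12)$value
  expect_equal(truncated_ellipsoid_volume(1, 1, 1 / 3) * 1000, oracle,
               tolerance = 1e-10)
  expect_equal(oracle, 80 * pi / 81, tolerance = 1e-12)
  # Monte-Carlo oracle for a prolate case
  set.seed(7)
  n <- 4e6
  x <- runif(n, -20, 20); y <- runif(n, -20, 20); z <- runif(n, -30, 10)
  inside <- (x^2 + y^2) / 20^2 + z^2 / 30^2 <= 1
  v_mc <- mean(inside) * 40 * 40 * 40 / 1000
  expect_equal(truncated_ellipsoid_volume(30, 20, 10), v_mc,
               tolerance = 2e-3)
  expect_error(truncated_ellipsoid_volume(10, 10, 11), "-a < h")
  expect_error(truncated_ellipsoid_volume(-1, 1, 0), "positive")
})

test_that("geometry solver reproduces the prescribed volumes to 1e-9", {
  g <- solve_geometry(50, 73.6)
  expect_equal(g$cavity_volume, 50, tolerance = 1e-9)
  expect_equal(g$wall_volume, 73.6, tolerance = 1e-9)
  expect_equal(g$a_endo / g$b_endo, 2, tolerance = 1e-12)
  expect_equal(g$base_height, g$a_endo / 3, tolerance = 1e-12)
  # degenerate zero-thickness shell
  g0 <- solve_geometry(60, 0)
  expect_equal(g0$thickness, 0)
  expect_equal(g0$a_epi, g0$a_endo)
  expect_error(solve_geometry(-1, 10), "positive")
})

test_that("calibrated default mesh holds the prescribed discrete volumes", {
  g <- solve_geometry(50, 73.6)
  mesh <- fixture("mesh_default", function() build_mesh(solve_geometry(50, 73.6)))
  expect_equal(cavity_volume_of(mesh), 50, tolerance = 1e-8)
  expect_equal(mesh_wall_volume(mesh), 73.6, tolerance = 1e-8)
  expect_true(all(mesh$elem_volumes > 0))
  expect_equal(mesh$n_elems, 12 * 6 * 7 + 12 * 7)
})

test_that("uncalibrated mesh converges to the analytic volumes on refinement", {
  g <- solve_geometry(50, 73.6)
  m1 <- build_mesh(g, 12, 6, 7, calibrate = FALSE)
  m2 <- build_mesh(g, 24, 12, 7, calibrate = FALSE)
  e1 <- abs(mesh_wall_volume(m1) - 73.6)
  e2 <- abs(mesh_wall_volume(m2) - 73.6)
  expect_lt(e2, 0.6 * e1)  # halves-or-better under 2x refinement
  c1 <- abs(cavity_volume_of(m1) - 50)
  c2 <- abs(cavity_volume_of(m2) - 50)
  expect_lt(c2, 0.6 * c1)
})

test_that("region labels partition the wall into 8 nonempty regions", {
  mesh <- fixture("mesh_default", function() build_mesh(solve_geometry(50, 73.6)))
  tab <- table(factor(mesh$elem_region, levels = 1:8))
  expect_true(all(tab > 0))
  expect_equal(sum(tab), mesh$n_elems)
  expect_equal(sort(unique(mesh$elem_layer)), 1:7)
})

test_that("cavity volume operator is translation invariant and cubic in scale", {
  mesh <- fixture("mesh_default", function() build_mesh(solve_geometry(50, 73.6)))
  v0 <- cavity_volume_of(mesh)
  u_tr <- rep(c(3.2, -1.5, 0.7), mesh$n_nodes)
  expect_equal(cavity_volume_of(mesh, u_tr), v0, tolerance = 1e-12)
  s <- 1.17
  u_sc <- as.numeric(t(mesh$nodes)) * (s - 1)
  expect_equal(cavity_volume_of(mesh, u_sc), v0 * s^3, tolerance = 1e-10)
  # independence of face ordering
  mesh2 <- mesh
  mesh2$endo_faces <- mesh$endo_faces[rev(seq_len(nrow(mesh$endo_faces))), ]
  expect_equal(cavity_volume_of(mesh2), v0, tolerance = 1e-12)
})

test_that("mesh preconditions are enforced", {
  g <- solve_geometry(50, 73.6)
  expect_error(build_mesh(g, n_circ = 6), "n_circ")
  expect_error(build_mesh(g, n_circ = 10), "n_circ")
  expect_error(build_mesh(g, n_long = 2), "n_long")
})
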