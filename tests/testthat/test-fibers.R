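test_that("helix angle reproduces every printed regional endpoint", {
  tab <- region_angle_table()
  spans <- list(
    "septum-basal" = c(-60, 40), "anterior-basal" = c(-40, 60),
    "lateral-basal" = c(-20, 50), "posterior-basal" = c(-20, 60),
    "septum-apical" = c(-50, 40), "anterior-apical" = c(-20, 60),
    "lateral-apical" = c(-20, 50), "posterior-apical" = c(-20, 60))
  for (nm in names(spans)) {
    id <- tab$region[tab$name == nm]
    expect_identical(helix_angle(id, 0), spans[[nm]][1])
    expect_identical(helix_angle(id, 1), spans[[nm]][2])
  }
  expect_equal(helix_angle(1, 0.5), -10)  # linear midpoint of (-60, 40)
  expect_error(helix_angle(1, 1.2), "\\[0, 1\\]")
  expect_error(helix_angle(99, 0.5), "region")
})

test_that("transverse angle is linear from -15 at apex to +15 at base", {
  expect_equal(transverse_angle(0), -15)
  expect_equal(transverse_angle(1), 15)
  expect_equal(transverse_angle(0.5), 0)
  expect_error(transverse_angle(-0.1), "\\[0, 1\\]")
})

test_that("local frame is orthonormal, outward and continuous", {
  geom <- solve_geometry(50, 73.6)
  # equatorial point on the +x axis, mid-wall
  pt <- c(geom$b_endo + geom$thickness / 2, 0, 0)
  fr <- local_frame(geom, pt)
  expect_equal(fr$circ, c(0, 1, 0), tolerance = 1e-9)
  expect_gt(fr$radial[1], 0.99)
  # orthonormality at random interior points
  set.seed(11)
  for (i in 1:50) {
    th <- runif(1, 0, 2 * pi); v <- runif(1, 0.1, 0.95); s <- runif(1)
    p <- drop(lvbulk:::shell_point(geom, th, v, s))
    fr <- local_frame(geom, p)
    M <- rbind(fr$circ, fr$long, fr$radial)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-10)
    # right-handed: circ x long = radial
    cxl <- c(fr$circ[2] * fr$long[3] - fr$circ[3] * fr$long[2],
             fr$circ[3] * fr$long[1] - fr$circ[1] * fr$long[3],
             fr$circ[1] * fr$long[2] - fr$circ[2] * fr$long[1])
    expect_equal(cxl, fr$radial, tolerance = 1e-9)
  }
  # continuity along a meridian: no sign flips
  vs <- seq(0.05, 0.98, length.out = 30)
  frames <- lapply(vs, function(v)
    local_frame(geom, drop(lvbulk:::shell_point(geom, 1.1, v, 0.5))))
  for (k in 2:length(frames)) {
    expect_gt(sum(frames[[k]]$radial * frames[[k - 1]]$radial), 0.9)
    expect_gt(sum(frames[[k]]$long * frames[[k - 1]]$long), 0.9)
  }
  expect_error(local_frame(geom, c(0, 0, -45)), "long axis")
})

test_that("assigned fibers are unit vectors matching the angle rules", {
  mesh <- fixture("mesh_default", function() build_mesh(solve_geometry(50, 73.6)))
  fib <- assign_fibers(mesh)
  expect_lt(max(abs(rowSums(fib$myofiber^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(fib$collagen^2) - 1)), 1e-12)
  # collagen is the radial frame vector
  expect_lt(max(abs(fib$collagen - fib$frame$radial)), 1e-14)
  # round trip: angles recovered from the stored vectors match the rule
  ang <- fiber_angles_of(fib)
  expect_lt(max(abs(ang$beta - fib$beta)), 1e-8)
  expect_lt(max(abs(ang$eta - fib$eta)), 1e-8)
  # beta lies within the printed regional span, eta within [-15, 15]
  tab <- region_angle_table()
  reg <- rep(mesh$elem_region, each = 8)
  lo <- pmin(tab$beta_epi[reg], tab$beta_endo[reg])
  hi <- pmax(tab$beta_epi[reg], tab$beta_endo[reg])
  expect_true(all(fib$beta >= lo - 1e-9 & fib$beta <= hi + 1e-9))
  expect_true(all(fib$eta >= -15 - 1e-9 & fib$eta <= 15 + 1e-9))
})

test_that("zero angles give circumferential fibers, 90 degrees longitudinal", {
  mesh <- fixture("mesh_default", function() build_mesh(solve_geometry(50, 73.6)))
  tab0 <- region_angle_table()
  tab0$beta_epi <- tab0$beta_endo <- 0
  fib0 <- assign_fibers(mesh, tab0)
  # eta still varies; compare against the in-plane circ direction tilted by eta
  er <- fib0$eta * pi / 180
  want <- cos(er) * fib0$frame$circ + sin(er) * fib0$frame$radial
  expect_lt(max(abs(fib0$myofiber - want)), 1e-12)

  tab9 <- tab0; tab9$beta_epi <- tab9$beta_endo <- 90
  fib9 <- assign_fibers(mesh, tab9)
  want9 <- cos(er) * fib9$frame$long + sin(er) * fib9$frame$radial
  expect_lt(max(abs(fib9$myofiber - want9)), 1e-12)
})

test_that("transmural helix profile is monotone within every region", {
  mesh <- fixture("mesh_default", function() build_mesh(solve_geometry(50, 73.6)))
  fib <- assign_fibers(mesh)
  beta_e <- fib$beta[seq(1, length(fib$beta), by = 8)]  # one qp per element
  for (r in 1:8) {
    sel <- mesh$elem_region == r
    # group by circumferential/longitudinal position, order by layer
    key <- paste(mesh$elem_theta[sel], mesh$elem_long[sel])
    for (k in unique(key)) {
      b <- beta_e[sel][key == k][order(mesh$elem_layer[sel][key == k])]
      expect_true(all(diff(b) <= 1e-9))  # epi-ward (increasing layer) decreases
    }
  }
})
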