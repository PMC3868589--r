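test_that("Ogden energy vanishes at rest, is isotropic and dilation-free", {
  prm <- ogden_params()
  expect_equal(ogden_energy(c(1, 1, 1), prm), 0)
  lam <- c(1.2, 0.9, 1.05)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(ogden_energy(lam[perm], prm), ogden_energy(lam, prm))
  # insensitive to pure dilation (isochoric measure)
  expect_equal(ogden_energy(1.3 * lam, prm), ogden_energy(lam, prm),
               tolerance = 1e-12)
  expect_error(ogden_energy(c(1, -1, 1), prm), "positive")
})

test_that("small-strain shear modulus equals (mu1 a1 + mu2 a2)/2 = 2083.4 kPa", {
  prm <- ogden_params()
  expect_equal(shear_modulus(prm), 2083.4, tolerance = 1e-6)
  # finite-difference of the energy under infinitesimal simple shear
  gam <- 1e-4
  F <- diag(3); F[1, 2] <- gam
  lam <- sqrt(eigen(crossprod(F), symmetric = TRUE, only.values = TRUE)$values)
  W <- ogden_energy(lam, prm)
  expect_equal(2 * W / gam^2, shear_modulus(prm), tolerance = 1e-4)
})

test_that("volumetric law has tangent bulk modulus K and pressure -K(J-1)", {
  expect_equal(volumetric_energy(1, 1000)$energy, 0)
  expect_equal(volumetric_energy(1, 1000)$pressure, 0)
  expect_equal(volumetric_energy(0.99, 1000)$pressure, 10)
  # analytic pressure equals -dU/dJ by central difference
  h <- 1e-7
  dU <- (volumetric_energy(1.05 + h, 800)$energy -
           volumetric_energy(1.05 - h, 800)$energy) / (2 * h)
  expect_equal(volumetric_energy(1.05, 800)$pressure, -dU, tolerance = 1e-6)
  # linear in K
  expect_equal(volumetric_energy(1.1, 2000)$energy,
               2 * volumetric_energy(1.1, 1000)$energy)
  expect_error(volumetric_energy(-1, 100), "positive")
  expect_error(volumetric_energy(1, 0), "'K'")
})

test_that("matrix stress is consistent with the energy to 1e-6", {
  prm <- ogden_params()
  expect_equal(matrix_stress(diag(3), prm, 1000), matrix(0, 3, 3))
  # pure dilation: hydrostatic stress only, from the volumetric term
  s <- 1.04
  sig <- matrix_stress(s * diag(3), prm, 700)
  expect_equal(sig, 700 * (s^3 - 1) * diag(3), tolerance = 1e-9)
  # random states: first Piola from sigma vs central difference of energy
  set.seed(3)
  for (trial in 1:20) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.06), 3)
    if (det(F) <= 0.2) next
    sig <- matrix_stress(F, prm, 1500)
    P <- det(F) * sig %*% t(solve(F))
    h <- 1e-6
    P_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P_fd[i, j] <- (lvbulk:::matrix_energy(Fp, prm, 1500) -
                       lvbulk:::matrix_energy(Fm, prm, 1500)) / (2 * h)
    }
    expect_equal(P, P_fd, tolerance = 1e-6)
  }
  expect_error(matrix_stress(matrix(0, 3, 3), prm, 100), "invertible")
})

test_that("matrix stress is frame indifferent", {
  set.seed(5)
  prm <- ogden_params()
  F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3)
  stopifnot(det(F) > 0)
  for (trial in 1:5) {
    Q <- random_rotation()
    expect_equal(matrix_stress(Q %*% F, prm, 900),
                 Q %*% matrix_stress(F, prm, 900) %*% t(Q),
                 tolerance = 1e-9)
  }
})

test_that("fiber reinforcement is uniaxial with Green-Lagrange strain", {
  f <- c(1, 0, 0)
  # rotation carries no fiber strain
  Q <- random_rotation()
  expect_equal(fiber_stress(Q, f, 100, 0.7), matrix(0, 3, 3),
               tolerance = 1e-12)
  # uniaxial stretch along the fiber: S_ff = vf Ef (lam^2 - 1)/2
  lam <- 1.15
  S <- fiber_stress(diag(c(lam, 1, 1)), f, 200, 0.7)
  expect_equal(S[1, 1], 0.7 * 200 * (lam^2 - 1) / 2)
  expect_equal(S[2, 2], 0)
  expect_equal(S[3, 3], 0)
  # zero modulus: passive matrix only
  expect_equal(fiber_stress(diag(c(2, 1, 1)), f, 0, 0.7), matrix(0, 3, 3))
  expect_error(fiber_stress(diag(3), c(1, 1, 0), 10, 0.1), "unit")
  expect_error(fiber_stress(diag(3), f, -5, 0.1), "non-negative")
})

test_that("constituent records enforce physical volume fractions", {
  cst <- fiber_constituents()
  expect_equal(cst$vf_myo, 0.7)
  expect_equal(cst$vf_col, 0.015)
  expect_equal(cst$e_col, 50)
  expect_error(fiber_constituents(vf_myo = 0.99, vf_col = 0.5), "fractions")
})
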