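#' Two-term Ogden parameters for the passive myocardial matrix
#'
#' Defaults: mu1 = 220 kPa, mu2 = 110 kPa, alpha1 = 11.77, alpha2 = 14.34.
#' The ground-state (small-strain) shear modulus is
#' `(mu1 alpha1 + mu2 alpha2) / 2`.
#'
#' @param mu1,mu2 shear-like moduli \[kPa\]
#' @param alpha1,alpha2 dimensionless exponents
#' @return object of class `ogden_params`
#' @export
ogden_params <- function(mu1 = 220, mu2 = 110, alpha1 = 11.77,
                         alpha2 = 14.34) {
  p <- structure(list(mu1 = mu1, mu2 = mu2, alpha1 = alpha1, alpha2 = alpha2),
                 class = "ogden_params")
  if (shear_modulus(p) <= 0)
    stop("ogden_params: sum(mu_i * alpha_i) must be positive")
  p
}

#' Ground-state shear modulus of an Ogden material
#' @param params an [ogden_params()]
#' @return shear modulus \[kPa\]
#' @export
shear_modulus <- function(params) {
  (params$mu1 * params$alpha1 + params$mu2 * params$alpha2) / 2
}

#' Fiber constituents of the wall composite
#'
#' Volume fractions and stiffness of the two embedded uniaxial fiber
#' families.  The myofiber modulus is the time-varying active elastance
#' `E_a(t)` supplied by the waveform schedule; the collagen modulus is
#' constant.  Collagen Poisson ratio and density are recorded for
#' completeness but unused: a uniaxial reinforcement has no transverse
#' response and the quasi-static model has no inertia.
#'
#' @param vf_myo myofiber volume fraction (default 0.7)
#' @param vf_col collagen volume fraction (default 0.015)
#' @param e_col collagen Young's modulus \[kPa\] (default 50)
#' @param nu_col collagen Poisson ratio (recorded, unused)
#' @param rho_col collagen density \[kg/m^3\] (recorded, unused)
#' @return object of class `fiber_constituents`
#' @export
fiber_constituents <- function(vf_myo = 0.7, vf_col = 0.015, e_col = 50,
                               nu_col = 0.49, rho_col = 1000) {
  if (vf_myo <= 0 || vf_myo >= 1 || vf_col < 0 || vf_col >= 1 ||
      vf_myo + vf_col >= 1)
    stop("fiber_constituents: volume fractions must lie in (0,1) and sum below 1")
  structure(list(vf_myo = vf_myo, vf_col = vf_col, e_col = e_col,
                 nu_col = nu_col, rho_col = rho_col),
            class = "fiber_constituents")
}

#' Isochoric Ogden strain-energy density
#'
#' `W = sum_p mu_p/alpha_p (lbar1^alpha_p + lbar2^alpha_p + lbar3^alpha_p - 3)`
#' evaluated on the isochoric stretches `lbar_i = J^(-1/3) lambda_i`, so the
#' energy is insensitive to pure dilation and vanishes in the reference
#' state.
#'
#' @param stretches principal stretches (length 3, positive)
#' @param params an [ogden_params()]
#' @return energy density \[kPa\]
#' @export
ogden_energy <- function(stretches, params = ogden_params()) {
  if (length(stretches) != 3 || any(stretches <= 0))
    stop("ogden_energy: need three positive principal stretches")
  J <- prod(stretches)
  lb <- stretches * J^(-1 / 3)
  with(params,
       mu1 / alpha1 * (sum(lb^alpha1) - 3) + mu2 / alpha2 * (sum(lb^alpha2) - 3))
}

#' Volumetric strain energy and pressure
#'
#' `U(J) = (K/2)(J - 1)^2`, the simplest convex volumetric law whose tangent
#' bulk modulus at `J = 1` is exactly `K`, so the identified `K` is directly
#' the tissue bulk modulus.  The hydrostatic pressure is
#' `p_vol = -dU/dJ = -K (J - 1)`.
#'
#' @param J volume ratio (positive)
#' @param K bulk modulus \[kPa\], positive
#' @return list with `energy` \[kPa\] and `pressure` \[kPa\]
#' @export
volumetric_energy <- function(J, K) {
  if (any(J <= 0)) stop("volumetric_energy: 'J' must be positive")
  if (K <= 0) stop("volumetric_energy: 'K' must be positive")
  list(energy = K / 2 * (J - 1)^2, pressure = -K * (J - 1))
}

# total strain-energy density of the matrix (isochoric + volumetric) at F
matrix_energy <- function(F, params = ogden_params(), K = 1000) {
  lam <- sqrt(eigen(crossprod(F), symmetric = TRUE, only.values = TRUE)$values)
  ogden_energy(lam, params) + volumetric_energy(det(F), K)$energy
}

#' Cauchy stress of the matrix material
#'
#' Spectral evaluation of the isochoric Ogden Kirchhoff stress plus the
#' volumetric part `K (J - 1) I`, returned as Cauchy stress
#' `sigma = tau / J`.  Consistent with numerical differentiation of
#' [ogden_energy()] + [volumetric_energy()] with respect to `F`.
#'
#' @param F deformation gradient (3x3, `det F > 0`)
#' @param params an [ogden_params()]
#' @param K bulk modulus \[kPa\]
#' @return 3x3 Cauchy stress \[kPa\]
#' @export
matrix_stress <- function(F, params = ogden_params(), K = 1000) {
  F <- as.matrix(F)
  J <- det(F)
  if (!all(dim(F) == c(3, 3)) || J <= 0)
    stop("matrix_stress: 'F' must be an invertible 3x3 gradient with det > 0")
  b <- tcrossprod(F)
  es <- eigen(b, symmetric = TRUE)
  lam2 <- es$values
  eps <- 0.5 * log(lam2)
  ebar <- mean(eps)
  tau_p <- numeric(3)
  for (p in list(c(params$mu1, params$alpha1), c(params$mu2, params$alpha2))) {
    x <- exp(p[2] * (eps - ebar))
    tau_p <- tau_p + p[1] * (x - mean(x))
  }
  tau <- es$vectors %*% diag(tau_p) %*% t(es$vectors)
  (tau + J * K * (J - 1) * diag(3)) / J
}

#' Second Piola-Kirchhoff stress of a uniaxial fiber family
#'
#' Linear uniaxial reinforcement in the fiber direction `f` (unit vector in
#' the reference configuration): with Green-Lagrange fiber strain
#' `eps = f . E_GL f`, the contribution is
#' `S = v_f E_f eps (f x f)` -- stiffness only along the fiber, acting in
#' both tension and compression.
#'
#' @param F deformation gradient (3x3)
#' @param direction unit fiber direction in the reference configuration
#' @param e_f fiber Young's modulus \[kPa\], non-negative
#' @param v_f fiber volume fraction
#' @return 3x3 second Piola-Kirchhoff stress contribution \[kPa\]
#' @export
fiber_stress <- function(F, direction, e_f, v_f) {
  direction <- as.numeric(direction)
  if (abs(sum(direction^2) - 1) > 1e-8)
    stop("fiber_stress: 'direction' must be a unit vector")
  if (e_f < 0) stop("fiber_stress: 'e_f' must be non-negative")
  a <- as.matrix(F) %*% direction
  eps <- (sum(a^2) - 1) / 2
  v_f * e_f * eps * tcrossprod(direction)
}
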