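#' Volume of a truncated ellipsoid
#'
#' Volume of the region `x^2/b^2 + y^2/b^2 + z^2/a^2 <= 1, z <= h`, i.e. a
#' prolate spheroid with polar semi-axis `a` and equatorial semi-axis `b`,
#' cut by a horizontal plane at height `h` above the centre (the apex sits
#' at `z = -a`).
#'
#' @param a polar (major) semi-axis \[mm\]
#' @param b equatorial (minor) semi-axis \[mm\]
#' @param h cut height above centre \[mm\], `-a < h <= a`
#' @return enclosed volume \[ml\]
#' @export
truncated_ellipsoid_volume <- function(a, b, h) {
  if (a <= 0 || b <= 0)
    stop("truncated_ellipsoid_volume: semi-axes must be positive")
  if (h > a || h <= -a)
    stop("truncated_ellipsoid_volume: need -a < h <= a")
  f <- function(z) a^2 * z - z^3 / 3
  pi * b^2 / a^2 * (f(h) - f(-a)) / 1000  # mm^3 -> ml
}

#' Solve the truncated-ellipsoid left-ventricle geometry
#'
#' Constructs the wall between two confocal-axis truncated ellipsoids sharing
#' a base plane, such that the endocardial (cavity) volume and the shell
#' (wall) volume match prescribed values.  The endocardial aspect ratio
#' `a_endo/b_endo` is fixed and the wall thickness is uniform
#' (`a_epi = a_endo + t`, `b_epi = b_endo + t`).  The base plane sits at
#' `z = a_endo * (2 * truncation_fraction - 1)`; the default fraction 2/3
#' retains two-thirds of the endocardial major axis (base at `a_endo/3`,
#' apex at `-a_endo`).
#'
#' @param cavity_volume target endocardial cavity volume \[ml\]
#' @param wall_volume target wall (shell) volume \[ml\]; `0` gives the
#'   degenerate zero-thickness shell
#' @param aspect_ratio endocardial `a/b` ratio (default 2)
#' @param truncation_fraction retained fraction of the endocardial major
#'   axis (default 2/3; 1/2 gives a hemispheroid cut at the equator)
#' @return object of class `lv_geometry` with fields `a_endo`, `b_endo`,
#'   `a_epi`, `b_epi`, `thickness`, `base_height` \[mm\], `cavity_volume`,
#'   `wall_volume` \[ml\], `aspect_ratio`, `truncation_fraction`
#' @export
solve_geometry <- function(cavity_volume = 50, wall_volume = 73.6,
                           aspect_ratio = 2, truncation_fraction = 2 / 3) {
  if (cavity_volume <= 0) stop("solve_geometry: 'cavity_volume' must be positive")
  if (wall_volume < 0) stop("solve_geometry: 'wall_volume' must be non-negative")
  if (aspect_ratio <= 0) stop("solve_geometry: 'aspect_ratio' must be positive")
  if (truncation_fraction <= 0.5 - 1e-12 || truncation_fraction >= 1)
    stop("solve_geometry: 'truncation_fraction' must lie in [0.5, 1)")

  AR <- aspect_ratio
  zf <- 2 * truncation_fraction - 1  # base height as fraction of a_endo
  cav <- function(b) truncated_ellipsoid_volume(AR * b, b, zf * AR * b)
  # cavity volume scales as b^3: closed-form root from a unit evaluation
  b_endo <- (cavity_volume / cav(1))^(1 / 3)
  a_endo <- AR * b_endo
  h <- zf * a_endo

  if (wall_volume == 0) {
    thick <- 0
  } else {
    shell <- function(t)
      truncated_ellipsoid_volume(a_endo + t, b_endo + t, h) -
        cavity_volume - wall_volume
    upper <- b_endo
    while (shell(upper) < 0) upper <- upper * 2
    thick <- stats::uniroot(shell, c(0, upper), tol = 1e-13)$root
  }

  g <- structure(
    list(a_endo = a_endo, b_endo = b_endo,
         a_epi = a_endo + thick, b_epi = b_endo + thick,
         thickness = thick, base_height = h,
         cavity_volume = truncated_ellipsoid_volume(a_endo, b_endo, h),
         wall_volume = truncated_ellipsoid_volume(a_endo + thick,
                                                  b_endo + thick, h) -
           truncated_ellipsoid_volume(a_endo, b_endo, h),
         aspect_ratio = AR, truncation_fraction = truncation_fraction),
    class = "lv_geometry")
  stopifnot(abs(g$cavity_volume - cavity_volume) <= 1e-9 * cavity_volume,
            wall_volume == 0 ||
              abs(g$wall_volume - wall_volume) <= 1e-9 * max(wall_volume, 1))
  g
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat("Truncated-ellipsoid LV geometry\n")
  cat(sprintf("  endocardium: a = %.3f mm, b = %.3f mm\n", x$a_endo, x$b_endo))
  cat(sprintf("  epicardium:  a = %.3f mm, b = %.3f mm (thickness %.3f mm)\n",
              x$a_epi, x$b_epi, x$thickness))
  cat(sprintf("  base plane at z = %.3f mm; apex at z = %.3f mm\n",
              x$base_height, -x$a_epi))
  cat(sprintf("  cavity %.4f ml, wall %.4f ml\n",
              x$cavity_volume, x$wall_volume))
  invisible(x)
}

# point on the interpolated shell surface at parametric (theta, v, s):
# theta: azimuth; v in [0,1] apex->base (uniform in polar angle);
# s in [0,1] endo->epi.  Returns the 3-vector (or matrix for vector input).
shell_point <- function(geom, theta, v, s) {
  psi_en <- acos(-geom$base_height / geom$a_endo)
  psi_ep <- acos(-geom$base_height / geom$a_epi)
  pe <- v * psi_en
  pp <- v * psi_ep
  E <- cbind(geom$b_endo * sin(pe) * cos(theta),
             geom$b_endo * sin(pe) * sin(theta),
             -geom$a_endo * cos(pe))
  P <- cbind(geom$b_epi * sin(pp) * cos(theta),
             geom$b_epi * sin(pp) * sin(theta),
             -geom$a_epi * cos(pp))
  (1 - s) * E + s * P
}
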