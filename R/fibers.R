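#' Regional helix-angle table
#'
#' Epicardial-to-endocardial helix-angle spans (degrees) for the eight
#' anatomical regions of the left-ventricular wall.  Region ids: 1
#' septum-basal, 2 anterior-basal, 3 lateral-basal, 4 posterior-basal, 5
#' septum-apical, 6 anterior-apical, 7 lateral-apical, 8 posterior-apical.
#'
#' @return data.frame with columns `region`, `name`, `beta_epi`, `beta_endo`
#' @export
region_angle_table <- function() {
  data.frame(
    region = 1:8,
    name = c("septum-basal", "anterior-basal", "lateral-basal",
             "posterior-basal", "septum-apical", "anterior-apical",
             "lateral-apical", "posterior-apical"),
    beta_epi = c(-60, -40, -20, -20, -50, -20, -20, -20),
    beta_endo = c(40, 60, 50, 60, 40, 60, 50, 60))
}

#' Helix angle at a transmural position
#'
#' Linear transmural interpolation of the regional helix angle from its
#' epicardial value at `s = 0` to its endocardial value at `s = 1`.
#'
#' @param region region id (1--8), see [region_angle_table()]
#' @param s transmural coordinate, 0 = epicardium, 1 = endocardium
#' @param table angle table (defaults to [region_angle_table()])
#' @return helix angle \[degrees\]
#' @export
helix_angle <- function(region, s, table = region_angle_table()) {
  if (any(s < 0 | s > 1)) stop("helix_angle: 's' must lie in [0, 1]")
  if (any(!region %in% table$region)) stop("helix_angle: unknown region id")
  i <- match(region, table$region)
  table$beta_epi[i] + s * (table$beta_endo[i] - table$beta_epi[i])
}

#' Transverse angle at a longitudinal position
#'
#' Linear from -15 degrees at the apex (`ell = 0`) through 0 at the equator
#' to +15 degrees at the base (`ell = 1`).
#'
#' @param ell longitudinal coordinate, 0 = apex, 1 = base
#' @return transverse angle \[degrees\]
#' @export
transverse_angle <- function(ell) {
  if (any(ell < 0 | ell > 1)) stop("transverse_angle: 'ell' must lie in [0, 1]")
  -15 + 30 * ell
}

# orthonormal local frame at parametric position (theta, v, s):
# rows circumferential, longitudinal, radial (outward).  Vectorized over rows
# of the input matrix cbind(theta, v, s).
frame_at <- function(geom, theta, v, s) {
  pt <- shell_point(geom, theta, v, s)
  a_s <- (1 - s) * geom$a_endo + s * geom$a_epi
  b_s <- (1 - s) * geom$b_endo + s * geom$b_epi
  n <- cbind(pt[, 1] / b_s^2, pt[, 2] / b_s^2, pt[, 3] / a_s^2)
  n <- n / sqrt(rowSums(n^2))
  cv <- cbind(-sin(theta), cos(theta), 0)
  # l = n x c (right-handed with c x l = n), points from apex toward base
  l <- cbind(n[, 2] * cv[, 3] - n[, 3] * cv[, 2],
             n[, 3] * cv[, 1] - n[, 1] * cv[, 3],
             n[, 1] * cv[, 2] - n[, 2] * cv[, 1])
  list(circ = cv, long = l, radial = n)
}

#' Local myocardial frame at a point inside the wall
#'
#' Recovers the orthonormal (circumferential, longitudinal, radial) triad of
#' the layered-shell parameterization at an arbitrary point strictly inside
#' the wall.  The radial vector is the outward wall normal of the
#' interpolated shell surface through the point; the circumferential vector
#' is the horizontal tangent; longitudinal completes the right-handed triad
#' (`circ x long = radial`).  Undefined on the long axis (apex
#' singularity).
#'
#' @param geom an [solve_geometry()] result
#' @param point numeric length-3 position \[mm\]
#' @return list with unit vectors `circ`, `long`, `radial` and the recovered
#'   parametric coordinates `theta`, `v`, `s`
#' @export
local_frame <- function(geom, point) {
  stopifnot(length(point) == 3)
  rho <- sqrt(point[1]^2 + point[2]^2)
  if (rho < 1e-9 * geom$a_endo)
    stop("local_frame: circumferential direction undefined on the long axis; ",
         "use the limiting frame of a neighbouring quadrature point")
  theta <- atan2(point[2], point[1])
  # Gauss-Newton on (v, s) for the shell parameterization through the point
  vs <- c(0.5, 0.5)
  target <- c(rho, point[3])
  fun <- function(vs) {
    p <- shell_point(geom, theta, vs[1], vs[2])
    c(sqrt(p[1]^2 + p[2]^2), p[3]) - target
  }
  for (it in 1:60) {
    r0 <- fun(vs)
    if (sqrt(sum(r0^2)) < 1e-11 * geom$a_endo) break
    h <- 1e-7
    Jc <- cbind((fun(vs + c(h, 0)) - r0) / h, (fun(vs + c(0, h)) - r0) / h)
    step <- tryCatch(solve(Jc, r0), error = function(e)
      stop("local_frame: parameterization is singular at this point"))
    vs <- vs - step
    vs <- pmin(pmax(vs, c(1e-9, -0.5)), c(1 - 1e-9, 1.5))
  }
  fr <- frame_at(geom, theta, vs[1], vs[2])
  list(circ = drop(fr$circ), long = drop(fr$long), radial = drop(fr$radial),
       theta = theta, v = vs[1], s = vs[2])
}

#' Assign myofiber and collagen direction fields
#'
#' Builds unit direction vectors at every quadrature point of the mesh.  The
#' myofiber direction is the circumferential vector rotated by the regional
#' helix angle about the radial axis (toward longitudinal) and then tilted
#' out of the tangent plane by the transverse angle (toward radial):
#' `f = cos(eta) (cos(beta) c + sin(beta) l) + sin(eta) n`.  The helix angle
#' is evaluated at the element's transmural layer midpoint (7 layers give
#' `s` in 1/14, 3/14, ..., 13/14 measuring from the epicardium); the
#' transverse angle at the quadrature point's longitudinal coordinate.  The
#' collagen direction is the radial basis vector.
#'
#' @param mesh an `lv_mesh`
#' @param table regional helix table, see [region_angle_table()]
#' @param constituents fiber volume fractions and moduli, see
#'   [fiber_constituents()]
#' @return object of class `fiber_field`: list with `(n_elems * 8) x 3`
#'   matrices `myofiber` and `collagen`, the per-quadrature-point angles
#'   `beta`, `eta` \[degrees\], the local frame, and `constituents`
#' @export
assign_fibers <- function(mesh, table = region_angle_table(),
                          constituents = fiber_constituents()) {
  if (any(is.na(mesh$elem_region)) || any(mesh$elem_region < 1))
    stop("assign_fibers: mesh has unlabeled elements")
  gp <- 1 / sqrt(3)
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  # 8 x 8 trilinear shape values, rows = quadrature points, cols = nodes
  N <- matrix(0, 8, 8)
  for (q in 1:8)
    N[q, ] <- 0.125 * (1 + sx * gp * sx[q]) * (1 + sy * gp * sy[q]) *
      (1 + sz * gp * sz[q])

  ne <- mesh$n_elems
  qp_theta <- as.vector(t(tcrossprod(mesh$elem_params[, , 1], N)))
  qp_v <- as.vector(t(tcrossprod(mesh$elem_params[, , 2], N)))
  qp_s_mesh <- as.vector(t(tcrossprod(mesh$elem_params[, , 3], N)))

  # transmural coordinate measured from the epicardium, at the layer midpoint
  s_layer <- 1 - (rep(mesh$elem_layer, each = 8) - 0.5) / mesh$n_layers
  beta <- helix_angle(rep(mesh$elem_region, each = 8), s_layer, table)
  eta <- transverse_angle(qp_v)

  fr <- frame_at(mesh$geom, qp_theta, qp_v, qp_s_mesh)
  br <- beta * pi / 180
  er <- eta * pi / 180
  myo <- cos(er) * (cos(br) * fr$circ + sin(br) * fr$long) + sin(er) * fr$radial
  structure(
    list(myofiber = myo, collagen = fr$radial,
         beta = beta, eta = eta, frame = fr,
         constituents = constituents),
    class = "fiber_field")
}

#' Recover helix and transverse angles from a fiber field
#'
#' Projects the stored myofiber unit vectors back onto the local frame:
#' `beta = atan2(f . long, f . circ)`, `eta = asin(f . radial)`.
#'
#' @param fibers a `fiber_field`
#' @return data.frame with columns `beta`, `eta` \[degrees\]
#' @export
fiber_angles_of <- function(fibers) {
  f <- fibers$myofiber
  fr <- fibers$frame
  data.frame(
    beta = atan2(rowSums(f * fr$long), rowSums(f * fr$circ)) * 180 / pi,
    eta = asin(pmin(pmax(rowSums(f * fr$radial), -1), 1)) * 180 / pi)
}
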