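#' Assemble the left-ventricle finite-element model
#'
#' Bundles mesh, fiber field, material parameters and boundary conditions
#' into a solvable model.  Boundary conditions follow the standard setup:
#' all base-plane nodes are fixed in the longitudinal (z) direction, the
#' base-centre pressure node is a fixed geometric point (it closes the
#' cavity and anchors the virtual lid), and the epicardium rests on a linear
#' elastic foundation of stiffness `k_found` (traction per unit normal
#' displacement) representing the surrounding organs.
#'
#' @param mesh an [build_mesh()] result
#' @param fibers a [assign_fibers()] fiber field (default: assigned from the
#'   mesh with the standard regional angle table)
#' @param matrix_params passive matrix Ogden parameters, [ogden_params()]
#' @param constituents fiber fractions/moduli, [fiber_constituents()]
#' @param k_found epicardial foundation stiffness \[kPa/mm\] (default 0.02)
#' @param pin_axis additionally fix the lateral motion of the long-axis
#'   (apex) nodes and the circumferential motion of one base node.  For
#'   axisymmetric verification problems these constraints are exact (the
#'   solution has no such motion) and remove the rigid modes that the soft
#'   foundation regularizes only weakly; off by default because the fibered
#'   ventricle twists physically.
#' @return object of class `lv_model`
#' @export
lv_model <- function(mesh, fibers = NULL, matrix_params = ogden_params(),
                     constituents = fiber_constituents(), k_found = 0.02,
                     pin_axis = FALSE) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(fibers)) fibers <- assign_fibers(mesh, constituents = constituents)
  if (k_found < 0) stop("lv_model: 'k_found' must be non-negative")
  fixed <- 3L * (mesh$base_nodes - 1L) + 3L  # u_z = 0 on the base plane
  if (pin_axis) {
    axis_nodes <- which(is.na(mesh$node_params[, 1]))
    node0 <- mesh$endo_ring[1]  # base-ring node on the +x axis
    fixed <- sort(unique(c(fixed,
                           3L * (axis_nodes - 1L) + 1L,
                           3L * (axis_nodes - 1L) + 2L,
                           3L * (node0 - 1L) + 2L)))
  }
  structure(
    list(mesh = mesh, fibers = fibers, matrix_params = matrix_params,
         constituents = constituents, k_found = k_found,
         fixed_dofs = fixed,
         free_dofs = setdiff(seq_len(3L * mesh$n_nodes), fixed),
         asm_cache = new.env(parent = emptyenv())),
    class = "lv_model")
}

#' @export
print.lv_model <- function(x, ...) {
  cat(sprintf("LV FE model: %d elements, %d nodes, %d free dofs\n",
              x$mesh$n_elems, x$mesh$n_nodes, length(x$free_dofs)))
  cat(sprintf("  foundation %.4g kPa/mm; %d constrained dofs (base u_z = 0)\n",
              x$k_found, length(x$fixed_dofs)))
  invisible(x)
}

#' Assemble residual and tangent at a displacement state
#'
#' Residual `R(u) = f_int(u) + f_foundation(u) - f_pressure(u)` and (if
#' requested) the consistent tangent, including the mean-dilatation
#' volumetric terms and the nonsymmetric follower-pressure load stiffness.
#'
#' @param model an [lv_model()]
#' @param u nodal displacements, length `3 * n_nodes` \[mm\]
#' @param p cavity pressure \[kPa\]
#' @param e_active active myofiber Young's modulus \[kPa\]
#' @param K bulk modulus \[kPa\]
#' @param tangent assemble the tangent matrix (default `TRUE`)
#' @param fiber_ref displacement field defining the strain reference of the
#'   active myofiber family (the configuration at the start of the current
#'   time step; the time-varying elastance stiffens the fibers about their
#'   operating point).  `NULL` means the stress-free reference.
#' @return list with `ok` (all element Jacobians positive), `residual`,
#'   `tangent` (a `dgCMatrix`, or `NULL`), `f_pressure` (assembled pressure
#'   force vector), `min_J`, `jbar_range`
#' @export
fe_assemble <- function(model, u, p, e_active, K, tangent = TRUE,
                        fiber_ref = NULL) {
  mesh <- model$mesh
  cst <- model$constituents
  mp <- model$matrix_params
  if (is.null(fiber_ref)) fiber_ref <- numeric(3L * mesh$n_nodes)
  out <- lv_assemble_cpp(
    mesh$nodes, u, fiber_ref, mesh$conn,
    model$fibers$myofiber, model$fibers$collagen,
    mp$mu1, mp$mu2, mp$alpha1, mp$alpha2,
    K, e_active, cst$vf_myo, cst$e_col, cst$vf_col,
    mesh$endo_faces, p, mesh$epi_faces, model$k_found, tangent)
  Kt <- NULL
  if (tangent && out$ok) {
    # the sparsity pattern is fixed by the mesh topology: build it once,
    # then only refill the numeric slot (triplet -> compressed-slot map)
    cache <- model$asm_cache
    nd <- 3L * mesh$n_nodes
    if (!is.null(cache$map) && length(cache$map) != length(out$x))
      rm("tpl", "map", envir = cache)  # pattern changed: rebuild
    if (is.null(cache$tpl)) {
      cache$tpl <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                                        dims = c(nd, nd))
      ti <- cache$tpl@i + 1
      tj <- rep.int(seq_len(nd), diff(cache$tpl@p))
      tkey <- ti + (tj - 1) * as.numeric(nd)
      cache$map <- findInterval(out$i + (out$j - 1) * as.numeric(nd), tkey)
    }
    Kt <- cache$tpl
    Kt@x <- lv_accum_cpp(out$x, cache$map, length(Kt@x))
  }
  list(ok = out$ok, residual = out$resid, tangent = Kt,
       f_pressure = out$fpress, vol_scale = out$vol_scale,
       min_J = out$min_J, jbar_range = out$jbar_range)
}

#' Solver controls
#'
#' @param rtol Newton convergence: residual norm relative to the applied
#'   pressure-force norm (default 1e-6)
#' @param atol absolute residual floor \[kPa mm^2\]
#' @param max_newton maximum Newton iterations per load increment
#' @param max_bisect maximum load-increment bisections before giving up
#' @param verbose print per-iteration diagnostics
#' @return list of class `solve_control`
#' @export
solve_control <- function(rtol = 1e-6, atol = 1e-8, max_newton = 30L,
                          max_bisect = 14L, verbose = FALSE) {
  structure(list(rtol = rtol, atol = atol, max_newton = max_newton,
                 max_bisect = max_bisect, verbose = verbose),
            class = "solve_control")
}

#' Stress-free initial state
#'
#' @param model an [lv_model()]
#' @return a `solve_state` at zero displacement, zero pressure
#' @export
initial_state <- function(model) {
  nd <- 3L * model$mesh$n_nodes
  structure(
    list(u = numeric(nd), p = 0, e_active = 0, K = NA_real_,
         fiber_ref = numeric(nd),
         volume = cavity_volume_of(model$mesh), newton_iters = 0L,
         residual_norm = 0, converged = TRUE),
    class = "solve_state")
}

# One Newton solve at fixed (p, e_active, K), starting from u.
# Returns list(converged, u, iters, rnorm).
newton_solve <- function(model, u, p, e_active, K, control, fiber_ref) {
  free <- model$free_dofs
  rn_prev <- Inf
  iters <- 0L
  for (it in seq_len(control$max_newton)) {
    asm <- fe_assemble(model, u, p, e_active, K, tangent = TRUE,
                       fiber_ref = fiber_ref)
    if (!asm$ok)
      return(list(converged = FALSE, u = u, iters = iters, rnorm = Inf))
    r <- asm$residual[free]
    rn <- sqrt(sum(r^2))
    fref <- max(sqrt(sum(asm$f_pressure^2)), 1e-3)
    # the volumetric force of a nearly incompressible state carries a
    # floating-point noise floor ~ eps * K * |dv/du|; residuals cannot be
    # driven below it
    floor_n <- 100 * .Machine$double.eps * asm$vol_scale
    tol_n <- max(control$rtol * fref + control$atol, floor_n)
    if (control$verbose)
      message(sprintf("    newton %2d: |R| = %.3e (ref %.3e, floor %.2e)",
                      it, rn, fref, floor_n))
    if (rn <= tol_n)
      return(list(converged = TRUE, u = u, iters = iters, rnorm = rn))
    lu <- tryCatch(Matrix::lu(asm$tangent[free, free, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(lu))
      return(list(converged = FALSE, u = u, iters = iters, rnorm = rn))
    A <- asm$tangent[free, free, drop = FALSE]
    du <- -as.numeric(Matrix::solve(lu, r))
    # iterative refinement: at extreme bulk/shear ratios the tangent is
    # ill-conditioned and a single LU backsolve stalls Newton near the
    # attainable residual floor
    for (ir in 1:2) {
      rr <- as.numeric(A %*% du) + r
      du <- du - as.numeric(Matrix::solve(lu, rr))
    }
    if (any(!is.finite(du)))
      return(list(converged = FALSE, u = u, iters = iters, rnorm = rn))
    # affine-invariant (natural-metric) line search: progress is measured by
    # |J^-1 R|, which removes the extreme curvature the near-incompressible
    # volumetric term induces in the plain residual norm
    ndu <- sqrt(sum(du^2))
    accepted <- FALSE
    for (alpha in c(1, 0.5, 0.25, 0.1, 0.04, 0.01)) {
      u_try <- u
      u_try[free] <- u_try[free] + alpha * du
      a2 <- fe_assemble(model, u_try, p, e_active, K, tangent = FALSE,
                        fiber_ref = fiber_ref)
      if (!a2$ok) next
      r_try <- a2$residual[free]
      rn_try <- sqrt(sum(r_try^2))
      if (rn_try <= tol_n) {
        u <- u_try
        accepted <- TRUE
        break
      }
      dn_try <- sqrt(sum(Matrix::solve(lu, r_try)^2))
      if (dn_try <= (1 - alpha / 4) * ndu) {
        u <- u_try
        accepted <- TRUE
        break
      }
    }
    iters <- it
    if (!accepted)
      return(list(converged = FALSE, u = u, iters = iters, rnorm = rn))
    rn_prev <- rn
  }
  list(converged = FALSE, u = u, iters = iters, rnorm = rn_prev)
}

#' Solve a quasi-static load step
#'
#' Newton--Raphson with backtracking line search, warm-started from the
#' previous state.  On failure the step is bisected: the hyperelastic
#' equilibrium depends only on the current load parameters, so the solver
#' follows a homotopy from the warm state's `(p, E_a, K)` to the target
#' (pressure and active modulus linearly, bulk modulus in log space, since
#' meaningful `K` values span several decades).
#'
#' @param model an [lv_model()]
#' @param state previous converged `solve_state` (or [initial_state()])
#' @param p target cavity pressure \[kPa\]
#' @param e_active target active myofiber modulus \[kPa\]
#' @param K bulk modulus \[kPa\], positive
#' @param control a [solve_control()]
#' @param fiber_ref active-fiber strain-reference displacement field
#'   (defaults to the stress-free reference), see [fe_assemble()]
#' @return a converged `solve_state` (error on divergence)
#' @export
solve_step <- function(model, state, p, e_active, K,
                       control = solve_control(), fiber_ref = NULL) {
  stopifnot(inherits(state, "solve_state"))
  if (K <= 0) stop("solve_step: 'K' must be positive")
  nd <- 3L * model$mesh$n_nodes
  if (is.null(fiber_ref)) fiber_ref <- numeric(nd)
  # the warm state is an equilibrium under ITS OWN fiber reference; the
  # homotopy interpolates the reference along with the loads so that s -> 0
  # recovers that equilibrium exactly
  ref0 <- state$fiber_ref %||% numeric(nd)
  p0 <- state$p
  ea0 <- state$e_active
  K0 <- if (is.finite(state$K) && state$K > 0) state$K else K
  u <- state$u
  total_iters <- 0L
  s_done <- 0
  s_step <- 1
  n_bisect <- 0L
  while (s_done < 1) {
    s <- min(1, s_done + s_step)
    p_s <- p0 + s * (p - p0)
    ea_s <- ea0 + s * (e_active - ea0)
    K_s <- exp(log(K0) + s * (log(K) - log(K0)))
    ref_s <- ref0 + s * (fiber_ref - ref0)
    res <- newton_solve(model, u, p_s, ea_s, K_s, control, ref_s)
    total_iters <- total_iters + res$iters
    if (res$converged) {
      u <- res$u
      s_done <- s
      s_step <- min(2 * s_step, 1)
    } else {
      s_step <- s_step / 2
      n_bisect <- n_bisect + 1L
      if (n_bisect > 4L * control$max_bisect || s_step < 2^-control$max_bisect)
        stop(sprintf(paste0(
          "solve_step: no convergence (p = %.4g kPa, E_a = %.4g kPa, ",
          "K = %.4g kPa; reached s = %.4g, |R| = %.3e after %d Newton ",
          "iterations)"), p, e_active, K, s_done, res$rnorm, total_iters))
    }
  }
  structure(
    list(u = u, p = p, e_active = e_active, K = K, fiber_ref = fiber_ref,
         volume = cavity_volume_of(model$mesh, u),
         newton_iters = total_iters, residual_norm = res$rnorm,
         converged = TRUE),
    class = "solve_state")
}

#' Relaxed (operating-point) solve under the stepwise elastance model
#'
#' With the active-fiber strain reference resetting at every time step, a
#' state held at fixed `(p, E_a, K)` creeps over successive steps until the
#' incremental fiber strain vanishes.  `solve_relaxed` iterates
#' solve-and-reset to that fixed point; it defines the operating state the
#' cardiac cycle starts from (the start-up transient of the stepwise model
#' is not part of the periodic cycle).
#'
#' @param model an [lv_model()]
#' @param state starting `solve_state`
#' @param p cavity pressure \[kPa\]
#' @param e_active active myofiber modulus \[kPa\]
#' @param K bulk modulus \[kPa\]
#' @param control a [solve_control()]
#' @param tol relative volume change between successive resets at which the
#'   state counts as settled
#' @param max_rounds cap on reset iterations
#' @return a converged, settled `solve_state`
#' @export
solve_relaxed <- function(model, state, p, e_active, K,
                          control = solve_control(), tol = 1e-3,
                          max_rounds = 30L) {
  st <- state
  for (round in seq_len(max_rounds)) {
    st2 <- solve_step(model, st, p, e_active, K, control, fiber_ref = st$u)
    dv <- abs(st2$volume - st$volume) / st2$volume
    st <- st2
    if (dv <= tol) break
  }
  st
}

#' Pressure preload ramp from the stress-free state
#'
#' The wall is stress free at zero cavity pressure; the cycle, however,
#' starts from an inflated configuration.  `preload` ramps the cavity
#' pressure from 0 to `p_target` in `n_ramp` increments (the active modulus
#' follows the elastance rule along the ramp) and returns the inflated
#' state plus the ramp history.
#'
#' @param model an [lv_model()]
#' @param p_target pressure at the start of the cycle \[kPa\]
#' @param K bulk modulus held during the ramp \[kPa\]
#' @param n_ramp number of ramp increments (default 10)
#' @param rule [active_elastance_rule()] for the modulus schedule
#' @param control a [solve_control()]
#' @return list with `state` (a `solve_state`) and `history` (data.frame of
#'   `p`, `volume` along the ramp)
#' @export
preload <- function(model, p_target, K, n_ramp = 10L,
                    rule = active_elastance_rule(),
                    control = solve_control()) {
  state <- initial_state(model)
  if (p_target < 0) stop("preload: 'p_target' must be non-negative")
  hist <- data.frame(p = 0, volume = state$volume)
  if (p_target == 0) {
    state$K <- K
    return(list(state = state, history = hist))
  }
  for (pk in seq(0, p_target, length.out = n_ramp + 1L)[-1L]) {
    state <- solve_step(model, state, pk, active_modulus(pk, rule), K, control,
                        fiber_ref = state$u)
    hist <- rbind(hist, data.frame(p = pk, volume = state$volume))
  }
  list(state = state, history = hist)
}
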