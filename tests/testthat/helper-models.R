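# Shared fixtures: built in code, sized for fast solves.

# small LV model for solver/inverse tests (coarse but well-shaped)
small_model <- function(n_circ = 8, n_long = 4, n_layers = 2, ...) {
  geom <- solve_geometry(50, 73.6)
  mesh <- build_mesh(geom, n_circ, n_long, n_layers)
  lv_model(mesh, ...)
}

# memoized expensive fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a minimal hand-made cycle_data data.frame
make_cycle <- function(t, p, v, rule = active_elastance_rule()) {
  structure(
    data.frame(t_s = t, p_kPa = p, v_ml = v,
               e_active_kPa = active_modulus(p, rule)),
    class = c("cycle_data", "data.frame"), rule = rule)
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# deformed wall volume (sum of element dilatations times reference volumes)
deformed_wall_volume <- function(mesh, u) {
  sum(lvbulk:::lv_jbar_cpp(mesh$nodes, u, mesh$conn) * mesh$elem_volumes)
}
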