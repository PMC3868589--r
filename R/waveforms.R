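#' Cardiac-cycle specification
#'
#' Describes one cardiac cycle of the left ventricle by its phase boundary
#' times and the printed anchor values of cavity pressure and volume.  The
#' seven phases are, in order: atrial systole, isovolumic contraction, rapid
#' ejection, reduced ejection, isovolumic relaxation, rapid filling and
#' reduced filling; `phase_times` gives the *end* time of each phase, the last
#' one equal to `cycle_length`.
#'
#' Only the phase-boundary values of the volume curve and a small set of
#' pressure anchors are fixed by the physiology data the reference cycle is
#' built from; the shape between anchors is interpolated (monotone cubic for
#' pressure, cubic smoothstep per phase for volume), so every anchor can be
#' replaced when a digitized curve is available.
#'
#' @param cycle_length cycle duration \[s\]
#' @param phase_times end times of the seven phases \[s\], strictly
#'   increasing, last equal to `cycle_length`
#' @param v_start cavity volume at the start of the cycle \[ml\]
#' @param edv end-diastolic volume, attained at end of atrial systole \[ml\]
#' @param esv end-systolic volume, attained at end of reduced ejection \[ml\]
#' @param p_peak peak cavity pressure \[kPa\]
#' @param p_anchors two-column matrix or data.frame `(t, p)` of pressure
#'   anchors \[s, kPa\]; must contain `t = 0`, `t = cycle_length`, and one
#'   anchor equal to `p_peak`
#' @param v_mid_ejection volume at the end of rapid ejection \[ml\]
#' @param v_end_rapid_fill volume at the end of rapid filling \[ml\]
#' @param n_samples number of samples over one cycle (including both ends)
#' @return an object of class `cycle_spec`
#' @seealso [reference_cycle_spec()], [generate_cycle()]
#' @export
cycle_spec <- function(cycle_length, phase_times, v_start, edv, esv,
                       p_peak, p_anchors, v_mid_ejection, v_end_rapid_fill,
                       n_samples = 41L) {
  p_anchors <- as.data.frame(p_anchors)
  names(p_anchors) <- c("t", "p")
  spec <- structure(
    list(cycle_length = cycle_length,
         phase_times = as.numeric(phase_times),
         v_start = v_start, edv = edv, esv = esv, p_peak = p_peak,
         p_anchors = p_anchors,
         v_mid_ejection = v_mid_ejection,
         v_end_rapid_fill = v_end_rapid_fill,
         n_samples = as.integer(n_samples)),
    class = "cycle_spec")
  validate_cycle_spec(spec)
  spec
}

validate_cycle_spec <- function(spec) {
  pt <- spec$phase_times
  if (length(pt) != 7L)
    stop("cycle_spec: 'phase_times' must list the end of all 7 phases")
  if (any(diff(c(0, pt)) <= 0))
    stop("cycle_spec: 'phase_times' must be strictly increasing from 0")
  if (abs(pt[7L] - spec$cycle_length) > 1e-12)
    stop("cycle_spec: last phase time must equal 'cycle_length'")
  if (!(spec$edv > spec$esv && spec$esv > 0))
    stop("cycle_spec: need edv > esv > 0 (got edv = ", spec$edv,
         ", esv = ", spec$esv, ")")
  if (spec$v_start > spec$edv)
    stop("cycle_spec: 'v_start' must not exceed 'edv'")
  if (spec$p_peak <= 0) stop("cycle_spec: 'p_peak' must be positive")
  pa <- spec$p_anchors
  if (any(diff(pa$t) <= 0)) stop("cycle_spec: pressure anchor times not increasing")
  if (min(pa$t) > 0 || max(pa$t) < spec$cycle_length - 1e-12)
    stop("cycle_spec: pressure anchors must span [0, cycle_length]")
  if (any(pa$p < 0)) stop("cycle_spec: negative anchor pressure")
  if (abs(max(pa$p) - spec$p_peak) > 1e-9)
    stop("cycle_spec: maximum pressure anchor must equal 'p_peak'")
  if (spec$n_samples < length(pt) + 1L)
    stop("cycle_spec: 'n_samples' must at least cover the phase breakpoints")
  invisible(spec)
}

#' Reference healthy-heart cycle specification
#'
#' The reference cycle used throughout: end-diastolic volume 130 ml,
#' end-systolic volume 50 ml (stroke volume 80 ml, ejection fraction 61.5%),
#' start-of-cycle volume 110 ml, peak pressure 16.93 kPa, phase boundaries at
#' 0.1, 0.21, 0.3, 0.43, 0.5 and 0.65 s with a 0.8 s cycle.  Interior
#' pressure anchors (aortic opening at 10.6 kPa, end-ejection 13.0 kPa,
#' diastolic 0.5--1.0 kPa) follow textbook healthy-human hemodynamics; the
#' pressure peak is placed mid rapid ejection at t = 0.26 s so that it falls
#' on the default 0.02 s sampling grid.
#'
#' @param n_samples number of samples over one cycle
#' @return a [cycle_spec()] object
#' @export
reference_cycle_spec <- function(n_samples = 41L) {
  cycle_spec(
    cycle_length = 0.8,
    phase_times = c(0.1, 0.21, 0.3, 0.43, 0.5, 0.65, 0.8),
    v_start = 110, edv = 130, esv = 50,
    p_peak = 16.93,
    p_anchors = data.frame(
      t = c(0, 0.1, 0.21, 0.26, 0.3, 0.43, 0.5, 0.65, 0.8),
      p = c(0.5, 1.0, 10.6, 16.93, 15.5, 13.0, 0.7, 0.55, 0.5)),
    v_mid_ejection = 60,
    v_end_rapid_fill = 105,
    n_samples = n_samples)
}

#' Active-elastance rule
#'
#' The active myofiber Young's modulus is taken proportional to the
#' instantaneous cavity pressure, `E_a = c_act * p`, with the
#' proportionality constant chosen so that the modulus at peak pressure
#' equals the physiological ceiling `e_max` (0.5 MPa).  For the reference
#' cycle `c_act = 500/16.93 = 29.53`, i.e. 29.5 to three significant figures.
#'
#' @param e_max maximum active myofiber Young's modulus \[kPa\]
#' @param p_peak peak cavity pressure the ceiling is anchored to \[kPa\]
#' @return object of class `active_elastance_rule` with fields `e_max`,
#'   `p_peak` and `c_act = e_max / p_peak`
#' @export
active_elastance_rule <- function(e_max = 500, p_peak = 16.93) {
  if (e_max <= 0 || p_peak <= 0)
    stop("active_elastance_rule: 'e_max' and 'p_peak' must be positive")
  structure(list(e_max = e_max, p_peak = p_peak, c_act = e_max / p_peak),
            class = "active_elastance_rule")
}

#' Active myofiber modulus from cavity pressure
#'
#' @param p cavity pressure(s) \[kPa\], non-negative
#' @param rule an [active_elastance_rule()]
#' @return active myofiber Young's modulus `c_act * p` \[kPa\]
#' @export
active_modulus <- function(p, rule = active_elastance_rule()) {
  if (any(p < 0)) stop("active_modulus: negative pressure")
  rule$c_act * p
}

# Monotone piecewise-cubic interpolation through an anchor table.  The
# anchors are split into maximal monotone runs (at local extrema) and each
# run gets its own Fritsch-Carlson monotone Hermite spline: FC guarantees
# monotonicity for monotone data, but not around interior extrema, where a
# single global fit can overshoot the anchored peak.
monotone_anchor_interp <- function(ta, ya) {
  n <- length(ta)
  sgn <- sign(diff(ya))
  breaks <- 1L
  cur <- 0
  for (k in seq_len(n - 1L)) {
    if (sgn[k] != 0 && cur != 0 && sgn[k] != cur) {
      breaks <- c(breaks, k)
      cur <- sgn[k]
    } else if (sgn[k] != 0 && cur == 0) cur <- sgn[k]
  }
  breaks <- c(breaks, n)
  funs <- lapply(seq_len(length(breaks) - 1L), function(r) {
    idx <- breaks[r]:breaks[r + 1L]
    stats::splinefun(ta[idx], ya[idx], method = "monoH.FC")
  })
  run_start <- ta[breaks[-length(breaks)]]
  function(t) {
    r <- pmin(findInterval(t, run_start), length(funs))
    out <- numeric(length(t))
    for (k in unique(r)) out[r == k] <- funs[[k]](t[r == k])
    out
  }
}

# cubic smoothstep between two anchors: monotone, C1, zero end slopes
smoothstep_interp <- function(t, t0, t1, y0, y1) {
  s <- (t - t0) / (t1 - t0)
  y0 + (y1 - y0) * (3 * s^2 - 2 * s^3)
}

# phase-boundary volumes implied by a cycle_spec, in phase order
phase_volume_anchors <- function(spec) {
  c(spec$v_start,          # t = 0
    spec$edv,              # end atrial systole
    spec$edv,              # end isovolumic contraction
    spec$v_mid_ejection,   # end rapid ejection
    spec$esv,              # end reduced ejection
    spec$esv,              # end isovolumic relaxation
    spec$v_end_rapid_fill, # end rapid filling
    spec$v_start)          # end reduced filling = cycle end
}

#' Generate a sampled cardiac cycle
#'
#' Samples pressure, target volume and the active myofiber modulus schedule
#' on a uniform time grid.  The volume curve is a cubic smoothstep within
#' each phase through the phase-boundary anchors and is *exactly* constant
#' during the two isovolumic phases; the pressure curve is a
#' Fritsch--Carlson monotone cubic through the anchor table, so every anchor
#' value (in particular the peak) is attained exactly.
#'
#' @param spec a [cycle_spec()]
#' @param rule an [active_elastance_rule()]; by default anchored to the
#'   spec's own peak pressure so that `max(e_active) = e_max`
#' @return object of class `cycle_data`: a data.frame with columns
#'   `t_s`, `p_kPa`, `v_ml`, `e_active_kPa`
#' @export
generate_cycle <- function(spec, rule = NULL) {
  validate_cycle_spec(spec)
  if (is.null(rule)) rule <- active_elastance_rule(p_peak = spec$p_peak)
  t <- seq(0, spec$cycle_length, length.out = spec$n_samples)

  pfun <- monotone_anchor_interp(spec$p_anchors$t, spec$p_anchors$p)
  p <- pmax(pfun(t), 0)

  bounds <- c(0, spec$phase_times)
  vanch <- phase_volume_anchors(spec)
  v <- numeric(length(t))
  phase <- pmin(findInterval(t, bounds, rightmost.closed = TRUE), 7L)
  for (k in 1:7) {
    idx <- which(phase == k)
    if (!length(idx)) next
    if (vanch[k] == vanch[k + 1]) {
      v[idx] <- vanch[k]          # isovolumic: constant to machine precision
    } else {
      v[idx] <- smoothstep_interp(t[idx], bounds[k], bounds[k + 1],
                                  vanch[k], vanch[k + 1])
    }
  }

  structure(
    data.frame(t_s = t, p_kPa = p, v_ml = v,
               e_active_kPa = active_modulus(p, rule)),
    class = c("cycle_data", "data.frame"),
    rule = rule, spec = spec)
}

#' Read a cardiac cycle from CSV
#'
#' Expects columns `t`, `p`, `v` (or the package's own `t_s`, `p_kPa`,
#' `v_ml`).  The active-modulus schedule is computed from the elastance rule;
#' unless a rule is supplied, the rule is anchored to the maximum loaded
#' pressure.
#'
#' @param path CSV file path
#' @param rule optional [active_elastance_rule()]
#' @return a `cycle_data` data.frame
#' @export
load_cycle_csv <- function(path, rule = NULL) {
  d <- utils::read.csv(path)
  nm <- names(d)
  pick <- function(a, b) if (a %in% nm) a else if (b %in% nm) b else
    stop("load_cycle_csv: missing column '", a, "' (or '", b, "')")
  t <- d[[pick("t", "t_s")]]
  p <- d[[pick("p", "p_kPa")]]
  v <- d[[pick("v", "v_ml")]]
  if (any(diff(t) <= 0)) stop("load_cycle_csv: time column not strictly increasing")
  if (any(p < 0)) stop("load_cycle_csv: negative pressure")
  if (any(v <= 0)) stop("load_cycle_csv: non-positive volume")
  if (is.null(rule)) rule <- active_elastance_rule(p_peak = max(p))
  structure(
    data.frame(t_s = t, p_kPa = p, v_ml = v,
               e_active_kPa = active_modulus(p, rule)),
    class = c("cycle_data", "data.frame"), rule = rule)
}

#' Write a cardiac cycle to CSV
#'
#' @param cycle a `cycle_data` data.frame
#' @param path output CSV path (columns `t_s, p_kPa, v_ml, e_active_kPa`)
#' @return `path`, invisibly
#' @export
write_cycle_csv <- function(cycle, path) {
  utils::write.csv(as.data.frame(cycle)[c("t_s", "p_kPa", "v_ml",
                                          "e_active_kPa")],
                   path, row.names = FALSE)
  invisible(path)
}
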