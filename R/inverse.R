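#' Settings for the inverse bulk-modulus identification
#'
#' @param rel_vol_tol per-step relative volume-matching tolerance (default
#'   0.01, i.e. the computed cavity volume must match the target within 1%)
#' @param K_min,K_max admissible bulk-modulus bracket \[kPa\] (defaults 0.01
#'   and 1e5)
#' @param max_iter maximum forward solves per time step
#' @param K_preload bulk modulus held during the preload ramp \[kPa\]
#'   (default: geometric mean of the bracket)
#' @param n_ramp preload ramp increments
#' @param control a [solve_control()]
#' @return list of class `inverse_settings`
#' @export
inverse_settings <- function(rel_vol_tol = 0.01, K_min = 0.01, K_max = 1e5,
                             max_iter = 60L, K_preload = sqrt(K_min * K_max),
                             n_ramp = 10L, control = solve_control()) {
  if (!(K_min > 0 && K_min < K_max))
    stop("inverse_settings: need 0 < K_min < K_max")
  if (rel_vol_tol <= 0) stop("inverse_settings: 'rel_vol_tol' must be positive")
  structure(list(rel_vol_tol = rel_vol_tol, K_min = K_min, K_max = K_max,
                 max_iter = as.integer(max_iter), K_preload = K_preload,
                 n_ramp = as.integer(n_ramp), control = control),
            class = "inverse_settings")
}

#' Identify the bulk modulus for a single time step
#'
#' Finds `K` such that the computed cavity volume matches `v_target` within
#' `rel_vol_tol`.  The cavity volume is monotone decreasing in `K` (a softer
#' volumetric response lets the pressurized wall dilate, enlarging the
#' cavity), so the root is found by a guarded secant iteration in `log K`,
#' falling back to log-space bisection once a sign-changing bracket is
#' established.  The bracket is grown from the warm-start guess by modest
#' geometric steps (factor 3) with warm-started continuation solves rather
#' than by cold endpoint evaluations: the identified waveform K(t) is
#' continuous, and conservative growth keeps the accepted modulus near the
#' smallest value satisfying the band instead of overshooting into the
#' insensitive near-incompressible plateau.  If the target is unreachable within
#' `[K_min, K_max]` the nearest endpoint is returned with a bracket-hit
#' flag -- saturation is reported, never silently accepted.
#'
#' @param model an [lv_model()]
#' @param state warm-start `solve_state` (previous step)
#' @param p cavity pressure \[kPa\]
#' @param e_active active myofiber modulus \[kPa\]
#' @param v_target target cavity volume \[ml\]
#' @param settings an [inverse_settings()]
#' @param K_guess starting bulk modulus \[kPa\] (typically the previous
#'   step's identified value)
#' @return list with `K`, `state`, `rel_err`, `n_solves`, `sens` (the
#'   estimated volume sensitivity `|dV/dlogK|` \[ml\] near the accepted
#'   modulus; where it is small the volume bounds rather than pins `K`) and
#'   `flag` (one of `"ok"`, `"bracket_hi"`, `"bracket_lo"`, `"maxit"`)
#' @export
identify_step <- function(model, state, p, e_active, v_target, settings,
                          K_guess, relaxed = FALSE) {
  if (v_target <= 0) stop("identify_step: 'v_target' must be positive")
  fiber_ref <- state$u  # elastance operating point: the step-start state
  tol <- settings$rel_vol_tol
  lo_K <- settings$K_min
  hi_K <- settings$K_max
  clamp <- function(K) min(max(K, lo_K), hi_K)

  evals <- list()
  eval_at <- function(K) {
    # warm start from the evaluated state nearest in log K
    from <- state
    if (length(evals)) {
      d <- vapply(evals, function(e) abs(log(e$K) - log(K)), 0)
      from <- evals[[which.min(d)]]$state
    }
    st <- if (relaxed)
      solve_relaxed(model, from, p, e_active, K, settings$control)
    else
      solve_step(model, from, p, e_active, K, settings$control,
                 fiber_ref = fiber_ref)
    e <- list(K = K, V = st$volume, state = st)
    evals[[length(evals) + 1L]] <<- e
    e
  }
  relerr <- function(e) (e$V - v_target) / v_target

  # |dV/dlogK| near the accepted evaluation, from the nearest distinct-K
  # evaluation (probing K/2 if the step accepted on its first solve)
  sens_at <- function(acc) {
    others <- Filter(function(e) abs(log(e$K) - log(acc$K)) > 1e-9, evals)
    if (!length(others)) others <- list(eval_at(clamp(acc$K / 2)))
    d <- vapply(others, function(e) abs(log(e$K) - log(acc$K)), 0)
    nb <- others[[which.min(d)]]
    abs((nb$V - acc$V) / (log(nb$K) - log(acc$K)))
  }
  done <- function(acc, flag)
    list(K = acc$K, state = acc$state, rel_err = relerr(acc),
         sens = sens_at(acc), n_solves = length(evals), flag = flag)

  e_cur <- eval_at(clamp(K_guess))
  if (abs(relerr(e_cur)) <= tol) return(done(e_cur, "ok"))

  # f(K) = V(K) - v_target is decreasing in K;
  # br_pos: largest K seen with f > 0, br_neg: smallest K seen with f < 0
  br_pos <- br_neg <- NULL
  note <- function(e) {
    if (relerr(e) > 0) {
      if (is.null(br_pos) || e$K > br_pos$K) br_pos <<- e
    } else {
      if (is.null(br_neg) || e$K < br_neg$K) br_neg <<- e
    }
  }
  note(e_cur)

  best <- e_cur
  for (it in seq_len(settings$max_iter)) {
    if (abs(relerr(e_cur)) < abs(relerr(best))) best <- e_cur
    if (abs(relerr(e_cur)) <= tol) return(done(e_cur, "ok"))
    if (is.null(br_neg) && !is.null(br_pos)) {
      # volume still above target even at the stiffest K tried: go up
      if (br_pos$K >= hi_K) return(done(br_pos, "bracket_hi"))
      e_cur <- eval_at(clamp(br_pos$K * 3))
    } else if (is.null(br_pos) && !is.null(br_neg)) {
      # volume below target even at the softest K tried: go down
      if (br_neg$K <= lo_K) return(done(br_neg, "bracket_lo"))
      e_cur <- eval_at(clamp(br_neg$K / 3))
    } else {
      # bracketed: secant in log K through the two bracket points,
      # safeguarded by bisection
      l1 <- log(br_pos$K); f1 <- relerr(br_pos)
      l2 <- log(br_neg$K); f2 <- relerr(br_neg)
      l_try <- l2 - f2 * (l2 - l1) / (f2 - f1)
      l_mid <- (l1 + l2) / 2
      margin <- 0.05 * abs(l2 - l1)
      if (!is.finite(l_try) ||
          l_try <= min(l1, l2) + margin || l_try >= max(l1, l2) - margin)
        l_try <- l_mid
      e_cur <- eval_at(exp(l_try))
    }
    note(e_cur)
  }
  if (abs(relerr(e_cur)) < abs(relerr(best))) best <- e_cur
  done(best, "maxit")
}

#' Identify the bulk-modulus waveform over a full cycle
#'
#' Runs the stress-free preload ramp to the start-of-cycle pressure, then
#' identifies `K` sequentially at every sample of the cycle, warm-starting
#' each step from the previous step's identified state and modulus.
#'
#' @param model an [lv_model()]
#' @param cycle a `cycle_data` data.frame ([generate_cycle()] or
#'   [load_cycle_csv()])
#' @param settings an [inverse_settings()]
#' @return object of class `lv_inverse`: a data.frame with one row per time
#'   step (`t_s`, `p_kPa`, `v_target_ml`, `v_fit_ml`, `rel_err`, `K_kPa`,
#'   `compressibility_per_kPa`, `n_solves`, `newton_iters`, `flag`) with the
#'   preload history attached
#' @export
identify_cycle <- function(model, cycle, settings = inverse_settings(),
                           start_relaxed = TRUE) {
  stopifnot(is.data.frame(cycle),
            all(c("t_s", "p_kPa", "v_ml", "e_active_kPa") %in% names(cycle)))
  n <- nrow(cycle)
  pre <- preload(model, cycle$p_kPa[1], K = settings$K_preload,
                 n_ramp = settings$n_ramp,
                 rule = attr(cycle, "rule") %||% active_elastance_rule(),
                 control = settings$control)
  state <- pre$state
  K_prev <- settings$K_preload

  rows <- vector("list", n)
  for (k in seq_len(n)) {
    res <- identify_step(model, state, cycle$p_kPa[k], cycle$e_active_kPa[k],
                         cycle$v_ml[k], settings, K_prev,
                         relaxed = start_relaxed && k == 1L)
    state <- res$state
    K_prev <- res$K
    rows[[k]] <- data.frame(
      t_s = cycle$t_s[k], p_kPa = cycle$p_kPa[k],
      v_target_ml = cycle$v_ml[k], v_fit_ml = state$volume,
      rel_err = res$rel_err, K_kPa = res$K,
      compressibility_per_kPa = 1 / res$K, sens_ml = res$sens,
      n_solves = res$n_solves, newton_iters = state$newton_iters,
      flag = res$flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lv_inverse", "data.frame")
  attr(out, "preload_history") <- pre$history
  attr(out, "settings") <- settings
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary of an inverse identification
#'
#' Reports the peak identified bulk modulus and compressibility, the time
#' of the peak, the fraction of the cycle during which the tissue is
#' operationally incompressible (compressibility below 5% of its cycle
#' maximum), and the target-volume derived EDV, ESV, stroke volume and
#' ejection fraction.  The peak is taken over the steps where the volume
#' actually pins the modulus: bracket-saturated steps are excluded, as are
#' steps whose volume sensitivity `|dV/dlogK|` falls below the
#' identifiability scale `rel_vol_tol * V_target` (there the acceptance
#' band covers a half-line in `K` and the per-step value only bounds the
#' modulus).
#'
#' @param object an `lv_inverse` result
#' @param sens_min identifiability threshold as a fraction of the target
#'   volume (default: the settings' `rel_vol_tol`, or 0.01)
#' @param ... unused
#' @return list of class `lv_inverse_summary`
#' @export
summary.lv_inverse <- function(object, sens_min = NULL, ...) {
  d <- as.data.frame(object)
  if (is.null(sens_min)) {
    st <- attr(object, "settings")
    sens_min <- if (!is.null(st)) st$rel_vol_tol else 0.01
  }
  ok <- d$flag == "ok"
  if (!is.null(d$sens_ml)) ok <- ok & d$sens_ml >= sens_min * d$v_target_ml
  idd <- if (any(ok)) d[ok, ] else d
  i_peak <- which.max(idd$K_kPa)
  comp <- d$compressibility_per_kPa
  incomp <- comp < 0.05 * max(comp)
  # trapezoid weights: each sample represents half of its two adjacent gaps
  tt <- d$t_s
  nt <- length(tt)
  w <- c(diff(tt) / 2, 0) + c(0, diff(tt) / 2)
  cycle_len <- max(tt) - min(tt)
  edv <- max(d$v_target_ml)
  esv <- min(d$v_target_ml)
  structure(
    list(K_peak_kPa = idd$K_kPa[i_peak],
         t_K_peak_s = idd$t_s[i_peak],
         compressibility_peak_per_kPa = max(idd$compressibility_per_kPa),
         incompressible_fraction = sum(w[incomp]) / cycle_len,
         max_rel_err = max(abs(d$rel_err)),
         n_flagged = sum(d$flag != "ok"),
         n_insensitive = sum(d$flag == "ok" & !ok),
         edv_ml = edv, esv_ml = esv, sv_ml = edv - esv,
         ef_pct = 100 * (edv - esv) / edv),
    class = "lv_inverse_summary")
}

#' @export
print.lv_inverse_summary <- function(x, ...) {
  cat("Inverse bulk-modulus identification\n")
  cat(sprintf("  peak K           : %.4g kPa at t = %.3g s\n",
              x$K_peak_kPa, x$t_K_peak_s))
  cat(sprintf("  peak compressibility: %.4g 1/kPa\n",
              x$compressibility_peak_per_kPa))
  cat(sprintf("  incompressible fraction of cycle: %.1f%%\n",
              100 * x$incompressible_fraction))
  cat(sprintf(
    "  max |rel. volume error|: %.3g%% (%d bracket-limited, %d low-sensitivity steps)\n",
    100 * x$max_rel_err, x$n_flagged, x$n_insensitive))
  cat(sprintf("  EDV %.4g ml, ESV %.4g ml, SV %.4g ml, Ef %.3g%%\n",
              x$edv_ml, x$esv_ml, x$sv_ml, x$ef_pct))
  invisible(x)
}

#' Forward cycle simulation with a prescribed bulk-modulus schedule
#'
#' Runs the preload ramp and then the pressure/active-modulus schedule of
#' `cycle` with a *known* `K(t)`, recording the computed cavity volume.
#' Used for self-consistency (parameter recovery) studies.
#'
#' @param model an [lv_model()]
#' @param cycle a `cycle_data` data.frame (its `v_ml` column is ignored)
#' @param K_schedule bulk modulus per time sample \[kPa\] (recycled if
#'   scalar)
#' @param settings an [inverse_settings()] (for preload and solver controls)
#' @return data.frame `t_s`, `p_kPa`, `e_active_kPa`, `K_kPa`, `v_ml`
#' @export
forward_cycle <- function(model, cycle, K_schedule,
                          settings = inverse_settings(),
                          start_relaxed = TRUE) {
  n <- nrow(cycle)
  K_schedule <- rep_len(K_schedule, n)
  if (any(K_schedule <= 0)) stop("forward_cycle: 'K_schedule' must be positive")
  pre <- preload(model, cycle$p_kPa[1], K = settings$K_preload,
                 n_ramp = settings$n_ramp,
                 rule = attr(cycle, "rule") %||% active_elastance_rule(),
                 control = settings$control)
  state <- pre$state
  v <- numeric(n)
  for (k in seq_len(n)) {
    state <- if (start_relaxed && k == 1L)
      solve_relaxed(model, state, cycle$p_kPa[k], cycle$e_active_kPa[k],
                    K_schedule[k], settings$control)
    else
      solve_step(model, state, cycle$p_kPa[k], cycle$e_active_kPa[k],
                 K_schedule[k], settings$control, fiber_ref = state$u)
    v[k] <- state$volume
  }
  data.frame(t_s = cycle$t_s, p_kPa = cycle$p_kPa,
             e_active_kPa = cycle$e_active_kPa, K_kPa = K_schedule, v_ml = v)
}
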