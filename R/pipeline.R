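#' Default run configuration
#'
#' Nested list of every tunable of the pipeline with its default value.
#' The defaults reproduce the reference experiment: the healthy-heart
#' reference cycle, the 50 ml / 73.6 ml geometry at coarse resolution, the
#' standard Ogden/fiber material set, and the 1% volume-matching rule.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    version = 1L,
    seed = 1L,
    output_dir = "results",
    cycle = list(
      source = "reference",  # "reference" or a CSV path
      n_samples = 41L,
      v_start = 110, edv = 130, esv = 50, p_peak = 16.93,
      v_mid_ejection = 60, v_end_rapid_fill = 105,
      cycle_length = 0.8,
      phase_times = c(0.1, 0.21, 0.3, 0.43, 0.5, 0.65, 0.8),
      p_anchor_t = c(0, 0.1, 0.21, 0.26, 0.3, 0.43, 0.5, 0.65, 0.8),
      p_anchor_p = c(0.5, 1.0, 10.6, 16.93, 15.5, 13.0, 0.7, 0.55, 0.5)),
    geometry = list(
      cavity_volume = 50, wall_volume = 73.6,
      aspect_ratio = 2, truncation_fraction = 2 / 3,
      n_circ = 12L, n_long = 6L, n_layers = 7L, calibrate = TRUE),
    materials = list(
      mu1 = 220, mu2 = 110, alpha1 = 11.77, alpha2 = 14.34,
      e_max = 500, vf_myo = 0.7, vf_col = 0.015, e_col = 50,
      nu_col = 0.49, rho_col = 1000),
    solver = list(
      k_found = 0.02, rtol = 1e-6, max_newton = 30L, n_ramp = 10L),
    inverse = list(
      rel_vol_tol = 0.01, K_min = 0.01, K_max = 1e5, max_iter = 60L))
}

validate_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad))
    stop("config: unknown top-level field(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), names(ref))) {
    if (is.list(ref[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(ref[[blk]]))
      if (length(bad))
        stop("config: unknown field(s) in '", blk, "': ",
             paste(bad, collapse = ", "))
    }
  }
  merged <- utils::modifyList(ref, config)
  num_pos <- function(blk, fld) {
    v <- merged[[blk]][[fld]]
    if (!is.numeric(v) || any(v <= 0))
      stop("config: '", blk, ".", fld, "' must be a positive number")
  }
  num_pos("geometry", "cavity_volume")
  num_pos("geometry", "wall_volume")
  num_pos("materials", "e_max")
  num_pos("inverse", "K_min")
  num_pos("inverse", "K_max")
  num_pos("cycle", "p_peak")
  if (merged$inverse$K_min >= merged$inverse$K_max)
    stop("config: 'inverse.K_min' must be below 'inverse.K_max'")
  merged
}

#' Load and validate a YAML run configuration
#'
#' Unspecified fields take their [default_config()] values; unknown fields
#' raise an error naming the offending block and field.
#'
#' @param path YAML file path (or `NULL` for the pure defaults)
#' @return validated configuration list
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  validate_config(cfg)
}

config_cycle <- function(config) {
  cc <- config$cycle
  if (!identical(cc$source, "reference"))
    return(load_cycle_csv(cc$source))
  spec <- cycle_spec(
    cycle_length = cc$cycle_length, phase_times = cc$phase_times,
    v_start = cc$v_start, edv = cc$edv, esv = cc$esv, p_peak = cc$p_peak,
    p_anchors = data.frame(t = cc$p_anchor_t, p = cc$p_anchor_p),
    v_mid_ejection = cc$v_mid_ejection,
    v_end_rapid_fill = cc$v_end_rapid_fill,
    n_samples = cc$n_samples)
  rule <- active_elastance_rule(e_max = config$materials$e_max,
                                p_peak = spec$p_peak)
  generate_cycle(spec, rule)
}

config_model <- function(config) {
  g <- config$geometry
  m <- config$materials
  geom <- solve_geometry(g$cavity_volume, g$wall_volume, g$aspect_ratio,
                         g$truncation_fraction)
  mesh <- build_mesh(geom, g$n_circ, g$n_long, g$n_layers, g$calibrate)
  cst <- fiber_constituents(m$vf_myo, m$vf_col, m$e_col, m$nu_col, m$rho_col)
  lv_model(mesh,
           matrix_params = ogden_params(m$mu1, m$mu2, m$alpha1, m$alpha2),
           constituents = cst, k_found = config$solver$k_found)
}

config_settings <- function(config) {
  iv <- config$inverse
  sv <- config$solver
  inverse_settings(rel_vol_tol = iv$rel_vol_tol, K_min = iv$K_min,
                   K_max = iv$K_max, max_iter = iv$max_iter,
                   n_ramp = sv$n_ramp,
                   control = solve_control(rtol = sv$rtol,
                                           max_newton = sv$max_newton))
}

#' Generate the waveforms of a configuration
#'
#' @param config a validated configuration ([load_run_config()])
#' @param out_csv optional output CSV path
#' @return the `cycle_data` data.frame, invisibly if written
#' @export
cmd_make_waveforms <- function(config = default_config(), out_csv = NULL) {
  set.seed(config$seed)
  cycle <- config_cycle(config)
  if (!is.null(out_csv)) {
    write_cycle_csv(cycle, out_csv)
    return(invisible(cycle))
  }
  cycle
}

#' Build the FE model of a configuration
#'
#' @param config a validated configuration
#' @param out_vtk optional VTK export path for the mesh and fiber field
#' @return the `lv_model`, invisibly if written
#' @export
cmd_build_model <- function(config = default_config(), out_vtk = NULL) {
  set.seed(config$seed)
  model <- config_model(config)
  if (!is.null(out_vtk)) {
    write_mesh_vtk(model$mesh, out_vtk, fibers = model$fibers)
    return(invisible(model))
  }
  model
}

#' Forward simulation with a prescribed bulk-modulus schedule
#'
#' @param config a validated configuration
#' @param K_schedule bulk modulus \[kPa\], scalar or per time sample
#' @param out_csv optional output CSV path
#' @return data.frame of the computed volume trace
#' @export
cmd_forward <- function(config = default_config(), K_schedule,
                        out_csv = NULL) {
  set.seed(config$seed)
  cycle <- config_cycle(config)
  model <- config_model(config)
  out <- forward_cycle(model, cycle, K_schedule, config_settings(config))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Run the inverse identification of a configuration
#'
#' End-to-end experiment: waveforms, model build, preload and per-step
#' identification of the bulk modulus.
#'
#' @param config a validated configuration
#' @param out_csv optional per-step result CSV path
#' @param out_json optional summary JSON path
#' @return an `lv_inverse` result
#' @export
cmd_identify <- function(config = default_config(), out_csv = NULL,
                         out_json = NULL) {
  set.seed(config$seed)
  cycle <- config_cycle(config)
  model <- config_model(config)
  res <- identify_cycle(model, cycle, config_settings(config))
  if (!is.null(out_csv))
    utils::write.csv(as.data.frame(res), out_csv, row.names = FALSE)
  if (!is.null(out_json)) {
    s <- summary(res)
    jsonlite::write_json(
      list(K_peak_kPa = s$K_peak_kPa, t_K_peak_s = s$t_K_peak_s,
           compressibility_peak_per_kPa = s$compressibility_peak_per_kPa,
           incompressible_fraction = s$incompressible_fraction,
           max_rel_err = s$max_rel_err, n_flagged = s$n_flagged,
           edv_ml = s$edv_ml, esv_ml = s$esv_ml, sv_ml = s$sv_ml,
           ef_pct = s$ef_pct),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Cross-dataset peak-modulus versus ejection-fraction table
#'
#' Runs [cmd_identify()] for each configuration and tabulates the peak
#' identified bulk modulus against the ejection fraction of the dataset.
#'
#' @param configs list of validated configurations (optionally named)
#' @param out_csv optional output CSV path
#' @return data.frame with one row per dataset: `dataset`, `K_peak_kPa`,
#'   `ef_pct`, `sv_ml`, `edv_ml`, `esv_ml`, `max_rel_err`, `n_flagged`
#' @export
cmd_compare <- function(configs, out_csv = NULL) {
  if (inherits(configs, "list") && !is.null(configs$version))
    configs <- list(configs)
  nm <- names(configs) %||% paste0("dataset_", seq_along(configs))
  nm[nm == ""] <- paste0("dataset_", which(nm == ""))
  rows <- lapply(seq_along(configs), function(i) {
    s <- summary(cmd_identify(configs[[i]]))
    data.frame(dataset = nm[i], K_peak_kPa = s$K_peak_kPa, ef_pct = s$ef_pct,
               sv_ml = s$sv_ml, edv_ml = s$edv_ml, esv_ml = s$esv_ml,
               max_rel_err = s$max_rel_err, n_flagged = s$n_flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
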