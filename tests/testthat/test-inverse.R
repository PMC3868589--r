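test_that("a guess already within tolerance is accepted after one solve", {
  model <- fixture("model_small", function() small_model())
  settings <- inverse_settings()
  st <- preload(model, 1, K = 100, n_ramp = 5)$state
  # target the volume this very state produces
  res <- identify_step(model, st, 1, 29.5, st$volume, settings, K_guess = 100)
  expect_identical(res$flag, "ok")
  # one identification solve; a second solve only probes the sensitivity
  expect_lte(res$n_solves, 2L)
  expect_equal(res$K, 100)
  expect_true(is.finite(res$sens))
})

test_that("stationary input yields a constant identified modulus", {
  model <- fixture("model_small", function() small_model())
  cy <- make_cycle(t = seq(0, 0.2, by = 0.05), p = rep(2, 5), v = rep(53, 5))
  settings <- inverse_settings(n_ramp = 5)
  res <- identify_cycle(model, cy, settings)
  expect_true(all(res$flag == "ok"))
  expect_true(all(abs(res$rel_err) <= settings$rel_vol_tol))
  # after the first step the modulus settles and stays put
  expect_lt(diff(range(res$K_kPa[-1])) / res$K_kPa[2], 1e-6)
})

test_that("isovolumic loading at rising pressure drives K sharply up", {
  model <- fixture("model_small", function() small_model())
  settings <- inverse_settings(rel_vol_tol = 1e-3, n_ramp = 5)
  st <- preload(model, 1, K = 100, n_ramp = 5)$state
  r1 <- identify_step(model, st, 1, 29.5, st$volume, settings, K_guess = 100)
  # same target volume under a much higher pressure: stiffen or saturate
  r2 <- identify_step(model, r1$state, 5, 147.5, r1$state$volume, settings,
                      r1$K)
  expect_true(r2$K > r1$K || r2$flag == "bracket_hi")
  if (r2$flag == "ok") expect_lte(abs(r2$rel_err), settings$rel_vol_tol)
})

test_that("unreachable targets saturate the bracket and are flagged", {
  model <- fixture("model_small", function() small_model())
  settings <- inverse_settings(K_min = 10, K_max = 1000, n_ramp = 5)
  st <- preload(model, 1, K = 100, n_ramp = 5)$state
  # far above anything attainable within [10, 1000] kPa at p = 1 kPa
  r <- identify_step(model, st, 1, 29.5, 120, settings, K_guess = 100)
  expect_identical(r$flag, "bracket_lo")
  expect_equal(r$K, 10)
  # far below the stiff-limit volume
  r2 <- identify_step(model, st, 1, 29.5, 40, settings, K_guess = 100)
  expect_identical(r2$flag, "bracket_hi")
  expect_equal(r2$K, 1000)
})

test_that("prescribed moduli are recovered from forward-simulated volumes", {
  model <- fixture("model_small", function() small_model())
  rule <- active_elastance_rule()
  tt <- seq(0, 0.3, by = 0.05)
  pp <- c(1, 3, 6, 10, 14, 16, 12)
  cy <- make_cycle(tt, pp, v = rep(60, 7), rule)
  K_true <- 10^seq(1.2, 3.6, length.out = 7)
  settings <- inverse_settings(rel_vol_tol = 5e-4, n_ramp = 5)
  fwd <- forward_cycle(model, cy, K_true, settings)
  cy$v_ml <- fwd$v_ml
  res <- identify_cycle(model, cy, settings)
  expect_true(all(res$flag == "ok"))
  # recovery wherever the volume meaningfully constrains the modulus
  sensitive <- res$sens_ml > 0.5
  expect_gte(sum(sensitive), 4)
  expect_lt(max(abs(res$K_kPa - K_true)[sensitive] / K_true[sensitive]), 0.05)
})

test_that("identification is deterministic", {
  model <- fixture("model_small", function() small_model())
  cy <- make_cycle(t = c(0, 0.1, 0.2), p = c(1, 4, 8), v = c(54, 55, 53))
  settings <- inverse_settings(n_ramp = 5)
  r1 <- identify_cycle(model, cy, settings)
  r2 <- identify_cycle(model, cy, settings)
  expect_identical(r1$K_kPa, r2$K_kPa)
  expect_identical(r1$v_fit_ml, r2$v_fit_ml)
})

test_that("summary reports volumes, ejection fraction and saturation", {
  cy <- generate_cycle(reference_cycle_spec())
  fake <- structure(
    data.frame(t_s = cy$t_s, p_kPa = cy$p_kPa, v_target_ml = cy$v_ml,
               v_fit_ml = cy$v_ml, rel_err = 0, K_kPa = 100,
               compressibility_per_kPa = 0.01, n_solves = 1L,
               newton_iters = 1L, flag = "ok"),
    class = c("lv_inverse", "data.frame"))
  s <- summary(fake)
  expect_equal(s$edv_ml, 130)
  expect_equal(s$esv_ml, 50)
  expect_equal(s$sv_ml, 80)
  expect_equal(s$ef_pct, 100 * 80 / 130, tolerance = 1e-10)
  # constant compressibility: never below 5% of its own maximum
  expect_equal(s$incompressible_fraction, 0)
  expect_equal(s$n_flagged, 0L)
})

test_that("settings invariants are validated", {
  expect_error(inverse_settings(K_min = 10, K_max = 1), "K_min < K_max")
  expect_error(inverse_settings(rel_vol_tol = 0), "positive")
  expect_error(identify_step(small_model(), NULL, 1, 1, -5,
                             inverse_settings(), 1), "positive")
})
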