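test_that("reference cycle spec carries the printed anchor values", {
  spec <- reference_cycle_spec()
  expect_equal(spec$edv, 130)
  expect_equal(spec$esv, 50)
  expect_equal(spec$v_start, 110)
  expect_equal(spec$p_peak, 16.93)
  expect_equal(spec$phase_times,
               c(0.1, 0.21, 0.3, 0.43, 0.5, 0.65, 0.8))
  expect_equal(spec$cycle_length, 0.8)
})

test_that("generated cycle honours stroke volume, plateaus and modulus cap", {
  cy <- generate_cycle(reference_cycle_spec())
  expect_equal(max(cy$v_ml) - min(cy$v_ml), 80)
  expect_equal(max(cy$v_ml), 130)
  expect_equal(min(cy$v_ml), 50)
  expect_equal(max(cy$p_kPa), 16.93)
  # isovolumic phases constant to machine precision
  iso1 <- cy$v_ml[cy$t_s >= 0.1 & cy$t_s <= 0.21]
  iso2 <- cy$v_ml[cy$t_s >= 0.43 & cy$t_s <= 0.5]
  expect_true(all(iso1 == 130))
  expect_true(all(iso2 == 50))
  # piecewise monotone per phase
  bounds <- c(0, reference_cycle_spec()$phase_times)
  for (k in 1:7) {
    vk <- cy$v_ml[cy$t_s >= bounds[k] & cy$t_s <= bounds[k + 1]]
    expect_true(all(diff(vk) >= 0) || all(diff(vk) <= 0))
  }
  # active modulus schedule
  rule <- attr(cy, "rule")
  expect_identical(max(cy$e_active_kPa), rule$c_act * max(cy$p_kPa))
  expect_lte(max(cy$e_active_kPa), 500)
  expect_true(all(cy$p_kPa >= 0) && all(cy$v_ml > 0))
})

test_that("resampling at doubled density reproduces the anchors exactly", {
  cy2 <- generate_cycle(reference_cycle_spec(n_samples = 81L))
  expect_equal(max(cy2$v_ml), 130)
  expect_equal(min(cy2$v_ml), 50)
  expect_equal(max(cy2$p_kPa), 16.93)
  expect_equal(max(cy2$e_active_kPa), 500)
})

test_that("active-elastance rule is proportional through the origin", {
  rule <- active_elastance_rule()
  expect_equal(active_modulus(0, rule), 0)
  # the proportionality constant rounds to the printed 29.5 at 3 s.f.
  expect_equal(signif(rule$c_act, 3), 29.5)
  # half of peak pressure maps to half of the modulus ceiling
  expect_equal(active_modulus(8.465, rule), 500 / 16.93 * 8.465)
  expect_equal(active_modulus(8.465, rule), 250, tolerance = 1e-12)
  expect_error(active_modulus(-1, rule), "negative")
})

test_that("invalid specs are rejected with diagnostics", {
  spec <- reference_cycle_spec()
  bad <- spec; bad$esv <- 200
  expect_error(lvbulk:::validate_cycle_spec(bad), "edv > esv")
  bad <- spec; bad$phase_times <- rev(spec$phase_times)
  expect_error(lvbulk:::validate_cycle_spec(bad), "increasing")
  bad <- spec; bad$n_samples <- 3L
  expect_error(lvbulk:::validate_cycle_spec(bad), "n_samples")
})

test_that("cycle CSV round-trips and rejects malformed input", {
  cy <- generate_cycle(reference_cycle_spec())
  f <- tempfile(fileext = ".csv")
  write_cycle_csv(cy, f)
  cy2 <- load_cycle_csv(f)
  expect_equal(cy2$v_ml, cy$v_ml)
  expect_equal(cy2$p_kPa, cy$p_kPa)
  expect_equal(cy2$e_active_kPa, cy$e_active_kPa, tolerance = 1e-12)

  d <- data.frame(t = c(0, 0.2, 0.1), p = 1:3, v = 4:6)
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(load_cycle_csv(f), "increasing")
  d <- data.frame(t = 1:3, p = 1:3)
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(load_cycle_csv(f), "missing column")
  d <- data.frame(t = 1:3, p = 1:3, v = c(1, -1, 1))
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(load_cycle_csv(f), "volume")

  # zero pressure throughout gives an identically zero modulus schedule
  d <- data.frame(t = 1:5, p = 0, v = 50)
  utils::write.csv(d, f, row.names = FALSE)
  cz <- load_cycle_csv(f, rule = active_elastance_rule())
  expect_true(all(cz$e_active_kPa == 0))
})
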