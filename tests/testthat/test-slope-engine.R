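test_that("segmentation places windows after the exclusion period", {
  samples <- data.frame(time_s = 0:1500, do_mg_l = 9, temp_c = 8)

  ## 10-min closed phase, one 6-min window at [240, 600)
  tr8 <- do_trace(samples,
                  phases = data.frame(start_s = 0, end_s = 600,
                                      phase = "closed"))
  w8 <- segment_cycles(tr8, quick_resp())
  expect_equal(nrow(w8), 1L)
  expect_equal(c(w8$start_s, w8$end_s), c(240, 600))

  ## 22-min closed phase, two 6-min windows at [240, 600) and [600, 960)
  samples22 <- data.frame(time_s = 0:1400, do_mg_l = 9, temp_c = 2)
  tr2 <- do_trace(samples22,
                  phases = data.frame(start_s = 0, end_s = 1320,
                                      phase = "closed"))
  w2 <- segment_cycles(tr2, quick_resp(closed_s = 1320,
                                       n_slopes_per_closed = 2L))
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$start_s, c(240, 600))
  expect_equal(w2$end_s, c(600, 960))

  ## a 5-min closed phase is too short: zero windows plus a warning
  tr5 <- do_trace(data.frame(time_s = 0:300, do_mg_l = 9, temp_c = 8),
                  phases = data.frame(start_s = 0, end_s = 300,
                                      phase = "closed"))
  expect_warning(w5 <- segment_cycles(tr5, quick_resp()), "no windows")
  expect_equal(nrow(w5), 0L)

  ## no closed phases at all: empty result with warning, not an error
  trf <- do_trace(data.frame(time_s = 0:100, do_mg_l = 9, temp_c = 8),
                  phases = data.frame(start_s = 0, end_s = 120,
                                      phase = "flush"))
  expect_warning(wf <- segment_cycles(trf, quick_resp()), "no closed")
  expect_equal(nrow(wf), 0L)
})

test_that("window slope fitting matches exact lines and flags degenerate input", {
  ## exact 0.6 mg/l decline over 6 min: slope -6 mg/l/h, r2 = 1
  tr <- linear_trace(-6, n = 361, dt = 1)
  f <- fit_window_slope(tr, c(0, 360))
  expect_equal(f$slope, -6, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_true(f$qc_pass)

  ## constant DO: slope 0 recorded with a QC flag, not an error
  trc <- linear_trace(0)
  fc <- fit_window_slope(trc, c(0, 360))
  expect_equal(fc$slope, 0)
  expect_false(fc$qc_pass)
  expect_match(fc$qc_reason, "variance")

  ## < 3 samples: QC failure naming the count
  f2 <- fit_window_slope(tr, c(0, 1.5))
  expect_false(f2$qc_pass)
  expect_match(f2$qc_reason, "2 sample")
})

test_that("noisy slope estimates fall within OLS sampling error", {
  set.seed(421)
  slope_true <- -4 / 3600     # mg/l per s
  n <- 73; dt <- 5
  miss <- 0L
  for (rep in 1:20) {
    t <- (0:(n - 1)) * dt
    y <- 9 + slope_true * t + rnorm(n, 0, 0.01)
    tr <- do_trace(data.frame(time_s = t, do_mg_l = y, temp_c = 8),
                   phases = data.frame(start_s = 0, end_s = 365,
                                       phase = "closed"))
    f <- fit_window_slope(tr, c(0, 365))
    se <- summary(lm(y ~ t))$coefficients["t", "Std. Error"] * 3600
    if (abs(f$slope - slope_true * 3600) > 3 * se) miss <- miss + 1L
  }
  expect_lte(miss, 2L)     # ~0.3% expected outside 3 s.e. per draw
})

test_that("background subtraction is exact and pass-through warns", {
  expect_equal(background_correct(-6.0, -0.2)$slope, -5.8)
  expect_equal(background_correct(-6.0, 0)$slope, -6.0)
  expect_warning(out <- background_correct(-6.0, NULL), "uncorrected")
  expect_false(out$background_corrected)
  expect_equal(out$slope, -6.0)
})

test_that("slope-to-MO2 conversion uses the displaced volume", {
  resp <- respirometer_config(volume_l = 6.15, fish_mass_kg = 0.15,
                              fish_density_kg_per_l = 1)
  expect_equal(effective_volume(resp), 6.0)
  out <- slope_to_mo2(-1.0, resp)
  expect_equal(out$mo2_abs_mg_h, 6.0)
  expect_equal(out$mo2_mgkg_h, 40.0)

  ## the standard chamber with the reference fish
  resp2 <- respirometer_config(volume_l = 6.1, fish_mass_kg = 0.146)
  expect_equal(effective_volume(resp2), 5.954)

  expect_equal(slope_to_mo2(0, resp)$mo2_abs_mg_h, 0)
})

test_that("extraction is linear in the decline rate and counts cycles", {
  resp <- quick_resp()
  st1 <- quick_state(params = metabolic_params(smr_ref = 40,
                                               activity_multiplier = 1))
  st2 <- quick_state(params = metabolic_params(smr_ref = 120,
                                               activity_multiplier = 1))
  tr1 <- simulate_do_trace(st1, resp, duration_h = 2, noise_sd = 0, seed = 1,
                           activity = FALSE)
  tr2 <- simulate_do_trace(st2, resp, duration_h = 2, noise_sd = 0, seed = 1,
                           activity = FALSE)
  r1 <- suppressMessages(extract_mo2(tr1, resp))
  r2 <- suppressMessages(extract_mo2(tr2, resp))
  expect_equal(r2$mo2_mgkg_h, 3 * r1$mo2_mgkg_h, tolerance = 1e-9)

  ## records per hour = 3600 / (flush + closed) * n_slopes for complete cycles
  expect_equal(nrow(r1), 2 * 3600 / (120 + 600) * 1)
  resp2 <- quick_resp(closed_s = 1320, n_slopes_per_closed = 2L)
  tr3 <- simulate_do_trace(st1, resp2, duration_h = 2.4, noise_sd = 0,
                           seed = 1, activity = FALSE)
  r3 <- suppressMessages(extract_mo2(tr3, resp2))
  expect_equal(nrow(r3), 2.4 * 3600 / (120 + 1320) * 2)
})

test_that("fitted slopes agree with an independent lm() re-computation", {
  st <- quick_state()
  resp <- quick_resp()
  tr <- simulate_do_trace(st, resp, duration_h = 2, noise_sd = 0.02, seed = 6)
  rec <- suppressMessages(extract_mo2(tr, resp))
  for (i in seq_len(nrow(rec))) {
    sel <- tr$samples$time_s >= rec$window_start_s[i] &
      tr$samples$time_s < rec$window_end_s[i]
    ref <- unname(coef(lm(do_mg_l ~ time_s, tr$samples[sel, ]))[2L]) * 3600
    expect_equal(rec$slope_do[i], ref, tolerance = 1e-10)
  }
})

test_that("positive corrected slopes are flagged, retained, excluded by default", {
  t <- 0:720
  up <- do_trace(data.frame(time_s = t, do_mg_l = 8 + t * 1e-4, temp_c = 8),
                 phases = data.frame(start_s = 0, end_s = 721,
                                     phase = "closed"))
  resp <- quick_resp(closed_s = 720)
  rec <- suppressMessages(extract_mo2(up, resp))
  expect_false(any(rec$qc_pass))
  expect_match(rec$qc_reason[1L], "positive")
  expect_lt(rec$mo2_mgkg_h[1L], 0)
  expect_error(estimate_smr(rec, min_records = 1), "too few")
})

test_that("MO2 record tables round-trip through CSV", {
  st <- quick_state()
  resp <- quick_resp()
  tr <- simulate_do_trace(st, resp, duration_h = 1, noise_sd = 0.01, seed = 2)
  rec <- suppressMessages(extract_mo2(tr, resp))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mo2_records(rec, path)
  back <- read_mo2_records(path)
  expect_identical(back$mo2_mgkg_h, rec$mo2_mgkg_h)
  expect_identical(back$qc_pass, rec$qc_pass)
})
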