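test_that("resting rate reproduces its closed forms", {
  p <- metabolic_params(smr_ref = 65, t_ref = 8, q10_acute = 4.3)

  ## reference condition: rate equals smr_ref at t_ref on any day, fed
  st_ref <- quick_state(temp_c = 8, params = p)
  expect_equal(true_resting_rate(st_ref, c(0, 10, 200)), rep(65, 3))

  ## no compensation: pure acute Q10 scaling at all days
  p0 <- metabolic_params(smr_ref = 65, q10_acute = 4.3,
                         compensation_frac = 0)
  st <- quick_state(temp_c = 2, params = p0)
  expect_equal(true_resting_rate(st, c(0, 30, 90)),
               rep(65 * 4.3^(-0.6), 3))

  ## starvation asymptote: 44% depression leaves 56% of smr_ref
  ps <- metabolic_params(starve_depression_frac = 0.44)
  sts <- quick_state(temp_c = 8, feeding = "starved", params = ps)
  expect_equal(true_resting_rate(sts, 1e7), 0.56 * 65, tolerance = 1e-9)

  ## compensation recovers the configured fraction of the acute drop
  pc <- metabolic_params(q10_acute = 4.3, compensation_frac = 0.63,
                         tau_acclim_days = 25)
  stc <- quick_state(temp_c = 2, params = pc)
  f_acute <- 4.3^(-0.6)
  f_comp <- f_acute + 0.63 * (1 - f_acute)
  expect_equal(true_resting_rate(stc, 1e6), 65 * f_comp, tolerance = 1e-9)
  expect_equal(true_resting_rate(stc, 25),
               65 * (f_acute + (f_comp - f_acute) * (1 - exp(-1))))

  expect_error(true_resting_rate(st_ref, -1), "precedes")
})

test_that("simulated traces are deterministic in the seed", {
  st <- quick_state()
  resp <- quick_resp()
  a <- simulate_do_trace(st, resp, duration_h = 1, noise_sd = 0.02, seed = 11)
  b <- simulate_do_trace(st, resp, duration_h = 1, noise_sd = 0.02, seed = 11)
  c <- simulate_do_trace(st, resp, duration_h = 1, noise_sd = 0.02, seed = 12)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples$do_mg_l, c$samples$do_mg_l))
})

test_that("a 24-h trace at the 8-degree cycle has 120 closed phases", {
  st <- quick_state(params = metabolic_params(activity_multiplier = 1))
  tr <- simulate_do_trace(st, quick_resp(), duration_h = 24, noise_sd = 0,
                          seed = 1, sample_dt_s = 10, activity = FALSE)
  expect_equal(sum(tr$phases$phase == "closed"), 120L)
})

test_that("DO is non-negative and non-increasing within noiseless closed phases", {
  st <- quick_state(temp_c = 2, feeding = "starved")
  tr <- simulate_do_trace(st, quick_resp(closed_s = 1320,
                                         n_slopes_per_closed = 2L),
                          duration_h = 6, noise_sd = 0, seed = 3,
                          sample_dt_s = 5)
  expect_true(all(tr$samples$do_mg_l >= 0))
  ph <- icresp:::sample_phase(tr)
  for (i in which(tr$phases$phase == "closed")) {
    sel <- tr$samples$time_s >= tr$phases$start_s[i] &
      tr$samples$time_s < tr$phases$end_s[i]
    expect_true(all(diff(tr$samples$do_mg_l[sel]) <= 1e-12))
  }
})

test_that("noiseless inactive trace inverts exactly through the slope engine", {
  ## slope * V_eff / mass must recover the generating rate to machine precision
  st <- quick_state(params = metabolic_params(activity_multiplier = 1))
  resp <- quick_resp()
  tr <- simulate_do_trace(st, resp, duration_h = 2, noise_sd = 0, seed = 5,
                          activity = FALSE)
  rec <- suppressMessages(extract_mo2(tr, resp))
  truth <- tr$meta$true_resting_rate
  expect_true(all(abs(rec$mo2_mgkg_h - truth) / truth < 1e-9))
})

test_that("activity bouts make the quantile robust where the mean is not", {
  st <- quick_state(params = metabolic_params())   # activity on
  resp <- quick_resp()
  tr <- simulate_do_trace(st, resp, duration_h = 25, noise_sd = 0, seed = 8,
                          sample_dt_s = 10)
  rec <- suppressMessages(extract_mo2(tr, resp))
  truth <- tr$meta$true_resting_rate
  smr <- estimate_smr(rec, window_h = 24)
  avg <- estimate_average_mo2(rec, window_h = 24)
  expect_lt(abs(smr - truth) / truth, 0.05)
  expect_gt(avg, truth * 1.02)     # the mean absorbs the activity bouts
  expect_lte(smr, avg)
})

test_that("background trace and correction recover the fish-only slope", {
  resp <- quick_resp()
  st <- quick_state(params = metabolic_params(activity_multiplier = 1))
  bg_rate <- 0.8     # mg O2 / h of microbial consumption
  tr <- simulate_do_trace(st, resp, duration_h = 2, noise_sd = 0, seed = 2,
                          background_mg_h = bg_rate, activity = FALSE)
  bg <- simulate_background_trace(resp, duration_h = 2, temp_c = 8,
                                  background_mg_h = bg_rate, noise_sd = 0,
                                  seed = 3)
  rec <- suppressMessages(extract_mo2(tr, resp, background = bg))
  expect_true(all(rec$background_corrected))
  truth <- tr$meta$true_resting_rate
  ## small residual remains because the empty chamber holds slightly more
  ## water than the occupied one; correction must still be accurate to <0.5%
  expect_true(all(abs(rec$mo2_mgkg_h - truth) / truth < 0.005))

  ## without correction the background inflates apparent uptake
  rec0 <- suppressMessages(extract_mo2(tr, resp))
  expect_true(all(rec0$mo2_mgkg_h > truth))
})

test_that("chase recovery trace yields MMR near the configured maximum", {
  resp <- quick_resp()
  st <- quick_state(params = metabolic_params(mmr_ref = 250,
                                              recovery_tau_min = 60))
  ch <- simulate_chase_recovery(st, resp, day = 0, seed = 4, noise_sd = 0)
  m <- detect_mmr(ch, resp, window_s = 90)
  expect_lt(abs(m$mmr - 250) / 250, 0.01)
  expect_equal(m$window[1L], 0)      # steepest window is the earliest

  ## recovery_tau -> infinity: uptake constant at mmr_ref
  st2 <- quick_state(params = metabolic_params(mmr_ref = 250,
                                               recovery_tau_min = 1e9))
  ch2 <- simulate_chase_recovery(st2, resp, day = 0, seed = 4, noise_sd = 0)
  m2 <- detect_mmr(ch2, resp, window_s = 90)
  expect_equal(m2$mmr, 250, tolerance = 1e-6)

  ## mmr_ref equal to resting rate: zero aerobic scope downstream
  p3 <- metabolic_params(smr_ref = 65, mmr_ref = 65, activity_multiplier = 1)
  st3 <- quick_state(params = p3)
  ch3 <- simulate_chase_recovery(st3, resp, day = 0, seed = 4, noise_sd = 0)
  m3 <- detect_mmr(ch3, resp, window_s = 90)
  expect_equal(aerobic_scope(65, m3$mmr), 0, tolerance = 1e-6)
})

test_that("acute cooling at day 0 yields the configured Q10 through the pipeline", {
  p <- metabolic_params(q10_acute = 4.3, activity_multiplier = 1)
  resp <- quick_resp()
  rates <- vapply(c(2, 8), function(temp) {
    st <- quick_state(temp_c = temp, params = p)
    tr <- simulate_do_trace(st, resp, duration_h = 2, day = 0, noise_sd = 0,
                            seed = 1, activity = FALSE)
    rec <- suppressMessages(extract_mo2(tr, resp))
    estimate_smr(rec, window_h = 2, min_records = 3)
  }, numeric(1))
  expect_lt(abs(q10(rates[1], rates[2], 2, 8) - 4.3) / 4.3, 0.02)
})

test_that("cohort simulation is seed-deterministic with treatment effects", {
  d <- cohort_design(n_per_group = 4, days = c(0, 30))
  a <- simulate_cohort(d, seed = 9)
  b <- simulate_cohort(d, seed = 9)
  c <- simulate_cohort(d, seed = 10)
  expect_identical(a$body, b$body)
  expect_identical(a$organs, b$organs)
  expect_false(identical(a$body$mass_g, c$body$mass_g))

  ## fed fish gain mass, starved fish lose it
  end <- a$body[a$body$day == 30, ]
  start <- a$body[a$body$day == 0, ]
  chg <- end$mass_g / start$mass_g[match(end$fish_id, start$fish_id)]
  feeding <- a$fish$feeding[match(end$fish_id, a$fish$fish_id)]
  expect_gt(mean(chg[feeding == "fed"]), 1)
  expect_lt(mean(chg[feeding == "starved"]), 1)
})

test_that("zero-noise, zero-effect designs give identical groups", {
  d <- cohort_design(n_per_group = 3, days = c(0, 90),
                     mass0_cv = 0, k0_sd = 0, sgr_sd = 0,
                     sgr_fed = 0.1, sgr_starved = 0.1,
                     fat_fed_end = 0.09, fat_starved_end = 0.09, fat0 = 0.09,
                     moisture_starved_end = 0.72,
                     starved_organ_mult = c(ventricle = 1, liver = 1,
                                            stomach = 1, pylorus = 1,
                                            intestine = 1),
                     organ_noise_cv = 0, conc_noise_cv = 0)
  co <- simulate_cohort(d, seed = 1)
  end <- co$body[co$body$day == 90, ]
  expect_equal(length(unique(round(end$mass_g, 9))), 1L)
  gut <- co$organs[co$organs$organ == "total_gut", ]
  expect_equal(length(unique(round(gut$organ_mass_g, 9))), 1L)
})
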