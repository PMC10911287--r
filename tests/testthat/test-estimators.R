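test_that("SMR quantile matches the order-statistic oracle", {
  ## worked example: 1..100 at p = 0.2 interpolates to 20.8
  expect_equal(estimate_smr(1:100), 20.8)
  expect_equal(oracle_quantile(1:100, 0.2), 20.8)

  ## all-equal records give the common value for any p
  for (p in c(0.05, 0.2, 0.5, 0.9)) {
    expect_equal(estimate_smr(rep(7.5, 40), quantile_p = p), 7.5)
  }

  ## random record sets match the oracle to floating precision
  set.seed(17)
  for (rep in 1:20) {
    x <- rlnorm(sample(25:200, 1), log(60), 0.3)
    p <- runif(1, 0.05, 0.95)
    expect_equal(estimate_smr(x, quantile_p = p),
                 oracle_quantile(x, p), tolerance = 1e-12)
  }

  ## the mean-below-p alternative averages the lowest fraction
  x <- 1:100
  q <- oracle_quantile(x, 0.2)
  expect_equal(estimate_smr(x, method = "mean_below_p"), mean(x[x <= q]))

  expect_error(estimate_smr(1:5), "too few.*5.*20")
  expect_error(estimate_smr(1:50, quantile_p = 1.2), "quantile_p")
})

test_that("average MO2 is the plain mean of usable records", {
  expect_equal(estimate_average_mo2(rep(3, 30)), 3)
  expect_equal(estimate_average_mo2(c(10, 20, 30), min_records = 3), 20)
  expect_error(estimate_average_mo2(1:3), "too few")
})

test_that("SMR and average honour the final analysis window", {
  ## two-phase record set: early high values must be ignored
  n <- 60
  rec <- data.frame(
    fish_id = "f", cycle = seq_len(n), slope_index = 1L,
    window_start_s = (seq_len(n) - 1) * 720,
    window_end_s = (seq_len(n) - 1) * 720 + 360,
    t_mid_s = (seq_len(n) - 1) * 720 + 180,
    slope_do = -1, r2 = 1, n = 70,
    mo2_abs_mg_h = 6, mo2_mgkg_h = rep(c(100, 50), each = n / 2),
    background_corrected = FALSE, qc_pass = TRUE, qc_reason = NA)
  class(rec) <- c("mo2_records", "data.frame")
  span_h <- (max(rec$t_mid_s) - min(rec$t_mid_s)) / 3600
  smr <- estimate_smr(rec, window_h = span_h / 2, min_records = 5)
  expect_equal(smr, 50)
  expect_equal(estimate_average_mo2(rec, window_h = span_h / 2,
                                    min_records = 5), 50)
  ## QC-failed records never enter the estimate
  rec$qc_pass[rec$mo2_mgkg_h == 50] <- FALSE
  expect_equal(estimate_smr(rec, window_h = 2 * span_h, min_records = 5), 100)
})

test_that("steepest-window MMR equals exhaustive search on structured traces", {
  ## one segment of doubled slope embedded in a shallower decline
  t <- 0:999
  y <- 10 - 0.002 * t
  y[t >= 400 & t < 600] <- y[t == 400] - 0.004 * (t[t >= 400 & t < 600] - 400)
  y[t >= 600] <- y[t == 600] - 0.002 * (t[t >= 600] - 600) + 0.004 * 0
  tr <- do_trace(data.frame(time_s = t, do_mg_l = y - min(y) + 1, temp_c = 8),
                 phases = data.frame(start_s = 0, end_s = 1000,
                                     phase = "closed"))
  resp <- quick_resp()
  got <- detect_mmr(tr, resp, window_s = 90)
  ora <- oracle_mmr_slope(tr, 90)
  expect_equal(got$slope / 3600, ora$slope, tolerance = 1e-9)
  expect_equal(got$window[1L], ora$start)
  expect_true(got$window[1L] >= 400 && got$window[1L] <= 510)

  ## single linear decline: first window wins, conversion is exact
  lin <- linear_trace(-6, n = 400, dt = 1)
  m <- detect_mmr(lin, resp, window_s = 90)
  expect_equal(m$window, c(0, 90))
  expect_equal(m$mmr, 6 * effective_volume(resp) / resp$fish_mass_kg,
               tolerance = 1e-9)

  ## windows never span a flush: the steep flush-adjacent join is ignored
  t2 <- 0:599
  y2 <- ifelse(t2 < 300, 10 - 0.001 * t2, 12 - 0.001 * (t2 - 300))
  tr2 <- do_trace(data.frame(time_s = t2, do_mg_l = y2, temp_c = 8),
                  phases = data.frame(start_s = c(0, 300, 360),
                                      end_s = c(300, 360, 600),
                                      phase = c("closed", "flush", "closed")))
  m2 <- detect_mmr(tr2, resp, window_s = 90)
  expect_equal(m2$slope, -3.6, tolerance = 1e-9)   # -0.001/s within a phase

  expect_error(detect_mmr(tr2, resp, window_s = 1000), "no closed segment")
})

test_that("steepest-window search equals brute force on random traces", {
  set.seed(99)
  for (rep in 1:10) {
    tr <- random_phase_trace(n = sample(400:1200, 1),
                             n_closed = sample(2:4, 1))
    got <- detect_mmr(tr, quick_resp(), window_s = 60)
    ora <- oracle_mmr_slope(tr, 60)
    expect_equal(got$slope / 3600, ora$slope, tolerance = 1e-9)
    expect_equal(got$window[1L], ora$start)
  }
})

test_that("Q10 reproduces its identities", {
  ## 77% decline between 14 and 2 degrees: Q10 = 3.4 at 2 s.f.
  expect_equal(round(q10(0.23, 1.00, 2, 14), 1), 3.4)
  ## argument order is normalized
  expect_equal(q10(1.00, 0.23, 14, 2), q10(0.23, 1.00, 2, 14))
  expect_equal(q10(5, 5, 2, 12), 1.0)
  expect_equal(q10(1, 2, 0, 10), 2.0)
  ## scale invariance in the rates
  expect_equal(q10(3 * 0.23, 3 * 1.0, 2, 14), q10(0.23, 1.0, 2, 14))
  ## inversion consistency: applying Q10 to r1 over (t2-t1) recovers r2
  qv <- q10(0.37, 1.21, 3, 11)
  expect_equal(0.37 * qv^((11 - 3) / 10), 1.21, tolerance = 1e-12)
  expect_error(q10(1, 2, 5, 5), "differ")
  expect_error(q10(-1, 2, 2, 8), "positive")
})

test_that("aerobic scope is the MMR-SMR difference with a flagged negative", {
  expect_equal(aerobic_scope(30, 130), 100)
  expect_equal(aerobic_scope(50, 50), 0)
  expect_warning(a <- aerobic_scope(100, 80), "negative")
  expect_equal(a, -20)
})

test_that("metabolic summary enforces internal consistency", {
  ms <- metabolic_summary("f1", 90, smr = 30, mo2_average = 40, mmr = 130,
                          n_measurements = 100L)
  expect_equal(ms$aas, 100)
  expect_output(print(ms), "SMR 30")
  expect_warning(metabolic_summary("f2", 0, smr = 50, mo2_average = 40),
                 "exceeds")
})
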