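test_that("a minimal CSV parses into a validated trace", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,do_mg_l,temp_c,phase",
               "0,9.5,8,closed", "1,9.49,8,closed", "2,9.48,8,closed"), path)
  tr <- read_do_trace(path)
  expect_s3_class(tr, "do_trace")
  expect_equal(nrow(tr$samples), 3L)
  expect_equal(nrow(tr$phases), 1L)
  expect_equal(tr$phases$phase, "closed")
  expect_equal(tr$meta$sample_interval_s, 1)
})

test_that("rejections name the violated invariant and location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,do_mg_l,temp_c", "0,9.5,8", "2,9.4,8", "1,9.3,8"), path)
  expect_error(read_do_trace(path), "strictly increasing.*row 3")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,oxygen,temp_c", "0,9.5,8"), path2)
  expect_error(read_do_trace(path2), "do_mg_l")

  expect_error(
    do_trace(data.frame(time_s = 0:1, do_mg_l = c(9, -1), temp_c = 8)),
    "non-negative")
  expect_error(
    do_trace(data.frame(time_s = 0:9, do_mg_l = 9, temp_c = 8),
             phases = data.frame(start_s = c(0, 3), end_s = c(5, 8),
                                 phase = "closed")),
    "overlap")
  expect_error(
    do_trace(data.frame(time_s = 0:9, do_mg_l = 9, temp_c = 8),
             phases = data.frame(start_s = 0, end_s = 5, phase = "swim")),
    "phase label")
})

test_that("write -> read round trip is exact, phases included", {
  st <- quick_state()
  tr <- simulate_do_trace(st, quick_resp(), duration_h = 1, noise_sd = 0.01,
                          seed = 42, sample_dt_s = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_do_trace(tr, path)
  back <- read_do_trace(path, phase_path = default_phase_path(path),
                        chamber_id = tr$chamber_id)
  expect_identical(back$samples$time_s, tr$samples$time_s)
  expect_identical(back$samples$do_mg_l, tr$samples$do_mg_l)
  expect_identical(back$samples$temp_c, tr$samples$temp_c)
  expect_identical(back$phases$start_s, tr$phases$start_s)
  expect_identical(back$phases$end_s, tr$phases$end_s)
  expect_identical(back$phases$phase, tr$phases$phase)

  ## chase_recovery phase survives the round trip
  tr2 <- do_trace(data.frame(time_s = 0:9, do_mg_l = 9, temp_c = 2),
                  phases = data.frame(start_s = c(0, 5), end_s = c(5, 10),
                                      phase = c("chase_recovery", "closed")))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_do_trace(tr2, path2)
  back2 <- read_do_trace(path2, phase_path = default_phase_path(path2))
  expect_identical(back2$phases$phase, c("chase_recovery", "closed"))
})

test_that("empty-sample trace writes a header-only file", {
  tr <- do_trace(data.frame(time_s = numeric(0), do_mg_l = numeric(0),
                            temp_c = numeric(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_do_trace(tr, path)
  expect_identical(readLines(path), "time_s,do_mg_l,temp_c")
})

test_that("boundary samples belong to the later half-open interval", {
  tr <- do_trace(data.frame(time_s = c(0, 60, 120, 180), do_mg_l = 9,
                            temp_c = 8),
                 phases = data.frame(start_s = c(0, 120), end_s = c(120, 240),
                                     phase = c("flush", "closed")))
  expect_identical(icresp:::sample_phase(tr),
                   c("flush", "flush", "closed", "closed"))
})

test_that("respirometer config validates physical constraints and reads YAML", {
  expect_error(respirometer_config(volume_l = -1), "volume")
  expect_error(respirometer_config(exclusion_s = 300, slope_window_s = 360,
                                   closed_s = 600), "exceeds closed_s")
  expect_error(respirometer_config(fish_mass_kg = 7, volume_l = 6.1),
               "smaller than chamber volume")

  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("volume_l: 6.1", "closed_s: 1320", "n_slopes_per_closed: 2",
               "fish_mass_kg: 0.146"), path)
  cfg <- read_respirometer_config(path)
  expect_equal(cfg$closed_s, 1320)
  expect_equal(cfg$n_slopes_per_closed, 2L)

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("volume_liters: 6.1", bad)
  expect_error(read_respirometer_config(bad), "unknown configuration key")
})

test_that("phase inference reconstructs the flush/closed alternation", {
  resp <- quick_resp()
  st <- quick_state()
  tr <- simulate_do_trace(st, resp, duration_h = 1, noise_sd = 0, seed = 1)
  bare <- do_trace(tr$samples, chamber_id = "x")
  inf <- infer_phases(bare, resp, start_phase = "flush")
  expect_equal(sum(inf$phases$phase == "closed"),
               sum(tr$phases$phase == "closed"))
  expect_equal(inf$phases$start_s[inf$phases$phase == "closed"],
               tr$phases$start_s[tr$phases$phase == "closed"])
})
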