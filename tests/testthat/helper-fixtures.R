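# shared fixtures and independent oracles

quick_resp <- function(...) {
  args <- list(volume_l = 6.1, flush_s = 120, closed_s = 600,
               exclusion_s = 240, slope_window_s = 360,
               n_slopes_per_closed = 1L, fish_mass_kg = 0.146)
  over <- list(...)
  args[names(over)] <- over
  do.call(respirometer_config, args)
}

quick_state <- function(temp_c = 8, feeding = "fed", mass_kg = 0.146,
                        params = metabolic_params(), seed = 1L) {
  fish_state(params, mass_kg = mass_kg,
             temp_schedule = data.frame(day = 0, temp_c = temp_c),
             feeding = feeding, rng_seed = seed)
}

# a trace that is an exact straight line within one closed phase
linear_trace <- function(slope_per_h, n = 361, dt = 1, do0 = 9.5, temp = 8) {
  t <- (seq_len(n) - 1) * dt
  do_trace(
    samples = data.frame(time_s = t, do_mg_l = do0 + slope_per_h * t / 3600,
                         temp_c = temp),
    phases = data.frame(start_s = 0, end_s = max(t) + dt, phase = "closed"))
}

# order-statistic quantile with linear interpolation, written independently
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive steepest-window search: per-start-index OLS via cov/var,
# independent of the prefix-sum implementation
oracle_mmr_slope <- function(trace, window_s, min_samples = 3L) {
  p <- trace$phases
  closed <- p[p$phase == "closed", , drop = FALSE]
  s <- trace$samples
  best_slope <- Inf
  best_start <- NA_real_
  for (i in seq_len(nrow(closed))) {
    sel <- which(s$time_s >= closed$start_s[i] & s$time_s < closed$end_s[i])
    if (length(sel) < min_samples) next
    t <- s$time_s[sel]
    y <- s$do_mg_l[sel]
    t_last <- t[length(t)]
    for (j in seq_along(t)) {
      if (t[j] + window_s > t_last + 1e-9) break
      k <- which(t >= t[j] & t < t[j] + window_s)
      if (length(k) < min_samples) next
      sl <- stats::cov(t[k], y[k]) / stats::var(t[k])
      if (is.infinite(best_slope) ||
          sl < best_slope - (abs(best_slope) * 1e-9 + 1e-15)) {
        best_slope <- sl
        best_start <- t[j]
      }
    }
  }
  list(slope = best_slope, start = best_start)
}

# random multi-phase trace with piecewise-linear DO plus noise
random_phase_trace <- function(n, n_closed = 3L, dt = 1) {
  closed_len <- floor(n / (2 * n_closed))
  t <- (seq_len(n) - 1) * dt
  slopes <- -stats::runif(n_closed, 0.5, 8) / 3600     # mg/l per s
  phase_tab <- list()
  do <- 9 + cumsum(stats::rnorm(n, 0, 0.003))
  t0 <- 0
  for (i in seq_len(n_closed)) {
    start <- t0 + closed_len * dt      # preceded by a "flush" gap
    end <- start + closed_len * dt
    sel <- t >= start & t < end
    do[sel] <- do[sel] + slopes[i] * (t[sel] - start)
    phase_tab[[i]] <- data.frame(start_s = start, end_s = end,
                                 phase = "closed")
    t0 <- end
  }
  do_trace(samples = data.frame(time_s = t, do_mg_l = pmax(do, 0), temp_c = 8),
           phases = do.call(rbind, phase_tab))
}

tiny_pipeline_config <- function(n_per_group = 2, days = 0,
                                 temps = c(2, 8), feeding = c("fed", "starved"),
                                 ...) {
  experiment_config(
    design = cohort_design(n_per_group = n_per_group, temps = temps,
                           feeding = feeding, days = days),
    trace_duration_h = 3, window_h = 3, min_records = 5,
    sample_dt_s = 10, chase_dt_s = 2, ...)
}
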