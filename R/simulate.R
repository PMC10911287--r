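#' Fish metabolic parameters for simulation
#'
#' Parameterizes the simulated fish's true oxygen uptake: an acute Q10 response
#' to temperature change, a gradual (exponential-in-time) thermal compensation
#' that recovers part of the acute change during acclimation, a starvation-
#' induced metabolic depression that develops with its own time constant, a
#' two-state activity process that intermittently multiplies uptake, and a
#' post-chase maximum with exponential recovery.
#'
#' Defaults describe a winter-active salmonid acclimating from 8 to 2 degrees C:
#' acute Q10 of 4.3 relaxing towards an acclimated Q10 of about 1.5
#' (`compensation_frac = 0.63` over a 6-degree step), compensation e-folding
#' time 25 days, an asymptotic 44% starvation depression developing with a
#' 12-day time constant, and a maximum uptake of 250 mg O2/kg/h decaying back to
#' resting with a 60-min time constant after an exhaustive chase.
#'
#' @param smr_ref resting (standard) mass-specific uptake at `t_ref` for a fed,
#'   fully acclimated fish (mg O2 kg^-1 h^-1).
#' @param t_ref reference temperature, degrees C.
#' @param q10_acute acute thermal sensitivity (>= 1).
#' @param compensation_frac fraction of the acute rate change recovered at full
#'   acclimation, in `[0, 1]`.
#' @param tau_acclim_days e-folding time of thermal compensation, days.
#' @param starve_depression_frac asymptotic fractional reduction of resting
#'   rate under starvation, in `[0, 1)`.
#' @param tau_starve_days e-folding time of starvation depression, days.
#' @param activity_multiplier uptake multiplier while spontaneously active
#'   (>= 1).
#' @param p_active_per_min,p_rest_per_min per-minute switch probabilities of
#'   the rest -> active and active -> rest transitions.
#' @param mmr_ref maximum mass-specific uptake immediately post-chase
#'   (mg O2 kg^-1 h^-1), at the fish's test temperature.
#' @param recovery_tau_min e-folding time of post-chase recovery, minutes.
#' @return An object of class `metabolic_params`.
#' @export
metabolic_params <- function(smr_ref = 65, t_ref = 8, q10_acute = 4.3,
                             compensation_frac = 0.63, tau_acclim_days = 25,
                             starve_depression_frac = 0.44,
                             tau_starve_days = 12,
                             activity_multiplier = 2.5,
                             p_active_per_min = 0.05, p_rest_per_min = 0.4,
                             mmr_ref = 250, recovery_tau_min = 60) {
  p <- list(smr_ref = smr_ref, t_ref = t_ref, q10_acute = q10_acute,
            compensation_frac = compensation_frac,
            tau_acclim_days = tau_acclim_days,
            starve_depression_frac = starve_depression_frac,
            tau_starve_days = tau_starve_days,
            activity_multiplier = activity_multiplier,
            p_active_per_min = p_active_per_min,
            p_rest_per_min = p_rest_per_min,
            mmr_ref = mmr_ref, recovery_tau_min = recovery_tau_min)
  p <- lapply(p, as.numeric)
  with(p, {
    if (smr_ref <= 0 || mmr_ref <= 0) stop("rates must be positive")
    if (q10_acute < 1) stop("q10_acute must be >= 1")
    if (compensation_frac < 0 || compensation_frac > 1) {
      stop("compensation_frac must be in [0, 1]")
    }
    if (starve_depression_frac < 0 || starve_depression_frac >= 1) {
      stop("starve_depression_frac must be in [0, 1)")
    }
    if (tau_acclim_days <= 0 || tau_starve_days <= 0 || recovery_tau_min <= 0) {
      stop("time constants must be positive")
    }
    if (activity_multiplier < 1) stop("activity_multiplier must be >= 1")
    if (p_active_per_min < 0 || p_active_per_min > 1 ||
        p_rest_per_min < 0 || p_rest_per_min > 1) {
      stop("switch probabilities must be in [0, 1]")
    }
  })
  structure(p, class = "metabolic_params")
}

#' Simulator ground truth for one fish
#'
#' Combines metabolic parameters with the individual's mass, temperature
#' history and feeding treatment. The temperature schedule is a step function:
#' row `(day, temp_c)` means the fish is at `temp_c` from `day` until the next
#' row. Thermal compensation restarts its clock at each temperature change;
#' the starvation clock starts at the first scheduled day.
#'
#' @param params a [metabolic_params()].
#' @param mass_kg body mass, kg.
#' @param temp_schedule data.frame `(day, temp_c)` with non-decreasing days.
#' @param feeding `"fed"` or `"starved"`.
#' @param rng_seed integer seed used when this state drives stochastic
#'   simulation.
#' @return An object of class `fish_state`.
#' @export
fish_state <- function(params, mass_kg = 0.146,
                       temp_schedule = data.frame(day = 0,
                                                  temp_c = params$t_ref),
                       feeding = c("fed", "starved"), rng_seed = 1L) {
  feeding <- match.arg(feeding)
  stopifnot(inherits(params, "metabolic_params"))
  if (mass_kg <= 0) stop("mass_kg must be positive")
  stopifnot(is.data.frame(temp_schedule),
            all(c("day", "temp_c") %in% names(temp_schedule)),
            nrow(temp_schedule) >= 1L)
  if (is.unsorted(temp_schedule$day)) {
    stop("temp_schedule days must be non-decreasing")
  }
  structure(list(params = params, mass_kg = as.numeric(mass_kg),
                 temp_schedule = temp_schedule[c("day", "temp_c")],
                 feeding = feeding, rng_seed = as.integer(rng_seed)),
            class = "fish_state")
}

#' @export
print.fish_state <- function(x, ...) {
  cat(sprintf("<fish_state> %.3f kg, %s, seed %d\n", x$mass_kg, x$feeding,
              x$rng_seed))
  cat("  temperature schedule: ",
      paste(sprintf("day %g -> %g C", x$temp_schedule$day,
                    x$temp_schedule$temp_c), collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' True resting oxygen uptake of a simulated fish
#'
#' The deterministic ground-truth resting rate at a given experiment day.
#' Relative to `smr_ref` at `t_ref`, the rate is scaled by an acute Q10 factor
#' `q10_acute^((T - t_ref)/10)` that relaxes exponentially (time constant
#' `tau_acclim_days`, clock restarting at each temperature change) towards the
#' compensated level, in which `compensation_frac` of the acute change has been
#' recovered. Starved fish are further multiplied by
#' `1 - starve_depression_frac * (1 - exp(-day / tau_starve_days))`.
#'
#' @param state a [fish_state()].
#' @param day experiment day (>= first scheduled day); vectorized.
#' @return Resting uptake, mg O2 kg^-1 h^-1.
#' @examples
#' st <- fish_state(metabolic_params(), feeding = "fed")
#' true_resting_rate(st, 0)   # reference condition: equals smr_ref
#' @export
true_resting_rate <- function(state, day) {
  stopifnot(inherits(state, "fish_state"))
  p <- state$params
  sched <- state$temp_schedule
  if (any(day < sched$day[1L])) {
    stop("day precedes the start of the temperature schedule")
  }
  seg <- findInterval(day, sched$day)
  temp <- sched$temp_c[seg]
  elapsed <- day - sched$day[seg]
  f_acute <- p$q10_acute^((temp - p$t_ref) / 10)
  f_comp <- f_acute + p$compensation_frac * (1 - f_acute)
  f <- f_acute + (f_comp - f_acute) * (1 - exp(-elapsed / p$tau_acclim_days))
  rate <- p$smr_ref * f
  if (state$feeding == "starved") {
    rate <- rate * (1 - p$starve_depression_frac *
                      (1 - exp(-day / p$tau_starve_days)))
  }
  rate
}

#' Oxygen saturation of fresh water
#'
#' Benson-Krause equilibrium concentration of dissolved oxygen in fresh water
#' at standard pressure, used as the flush-phase asymptote.
#'
#' @param temp_c water temperature, degrees C.
#' @return Saturation DO, mg O2 per litre.
#' @export
do_saturation <- function(temp_c) {
  tk <- temp_c + 273.15
  exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
        1.2438e10 / tk^3 - 8.621949e11 / tk^4)
}

## run code with a private RNG stream; global .Random.seed untouched
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

## two-state (rest/active) Markov chain at 1-min resolution; returns logical
simulate_activity <- function(n_min, p_active, p_rest) {
  if (n_min <= 0L) return(logical(0))
  act <- logical(n_min)
  pi_active <- if (p_active + p_rest > 0) p_active / (p_active + p_rest) else 0
  u <- stats::runif(n_min)
  act[1L] <- u[1L] < pi_active
  if (n_min > 1L) {
    for (i in 2:n_min) {
      act[i] <- if (act[i - 1L]) u[i] >= p_rest else u[i] < p_active
    }
  }
  act
}

## integrate chamber DO over sample grid given per-interval volumetric
## consumption c (mg/l/s during [t_i, t_i+dt)) and per-sample phase
integrate_do <- function(t, c_per_s, phase, dt, sat, flush_k) {
  n <- length(t)
  do <- numeric(n)
  do[1L] <- sat
  r <- rle(phase)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  for (j in seq_along(r$values)) {
    i1 <- idx_start[j]; i2 <- idx_end[j]
    if (r$values[j] == "closed") {
      if (i2 > i1) {
        do[(i1 + 1L):i2] <- do[i1] - cumsum(c_per_s[i1:(i2 - 1L)]) * dt
      }
      carry <- do[i2] - c_per_s[i2] * dt
    } else {
      ## flush: dDO/dt = k (sat - DO) - c  =>  per-step closed form
      ek <- exp(-flush_k * dt)
      if (i2 > i1) {
        for (i in i1:(i2 - 1L)) {
          s_star <- sat - c_per_s[i] / flush_k
          do[i + 1L] <- s_star + (do[i] - s_star) * ek
        }
      }
      s_star <- sat - c_per_s[i2] / flush_k
      carry <- s_star + (do[i2] - s_star) * ek
    }
    if (j < length(r$values)) do[i2 + 1L] <- carry
  }
  pmax(do, 0)
}

#' Simulate an intermittent-closed respirometry trace
#'
#' Generates the dissolved-oxygen record of one fish in one chamber over
#' alternating flush/closed cycles. During closed phases DO declines at
#' `(uptake * mass + background) / V_eff`; during flushes it relaxes towards
#' saturation. Uptake is the fish's [true_resting_rate()] at `day` (the
#' metabolic state is treated as frozen over the trace — acclimation and
#' starvation clocks advance between measurement days, not within a trial),
#' multiplied by `activity_multiplier` during active bouts of a 1-min
#' rest/active Markov chain. I.i.d. Gaussian measurement noise is added to the
#' observed DO. Identical seeds give identical traces.
#'
#' @param state a [fish_state()].
#' @param resp a [respirometer_config()]; its `fish_mass_kg` should match
#'   `state$mass_kg` (it is overridden to the state's mass with a warning
#'   otherwise).
#' @param duration_h trace duration, hours.
#' @param day experiment day at which the trace is recorded.
#' @param noise_sd optode noise standard deviation, mg O2 per litre.
#' @param seed integer seed; defaults to the state's `rng_seed`.
#' @param sample_dt_s sampling interval, seconds.
#' @param background_mg_h microbial background respiration of the chamber,
#'   mg O2 per hour (absolute).
#' @param activity logical; simulate spontaneous activity bouts.
#' @return A [do_trace()] whose `meta` records the ground truth
#'   (`true_resting_rate`, activity minutes, background).
#' @export
simulate_do_trace <- function(state, resp, duration_h = 24, day = 0,
                              noise_sd = 0.01, seed = state$rng_seed,
                              sample_dt_s = 5, background_mg_h = 0,
                              activity = TRUE) {
  stopifnot(inherits(state, "fish_state"),
            inherits(resp, "respirometer_config"))
  if (duration_h <= 0) stop("duration_h must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (abs(resp$fish_mass_kg - state$mass_kg) > 1e-12) {
    warning("respirometer fish_mass_kg differs from state mass; using state mass")
    resp$fish_mass_kg <- state$mass_kg
  }
  v_eff <- effective_volume(resp)
  sched <- state$temp_schedule
  temp <- sched$temp_c[findInterval(day, sched$day)]
  sat <- do_saturation(temp)
  rest <- true_resting_rate(state, day)

  dt <- sample_dt_s
  n <- floor(duration_h * 3600 / dt)
  t <- (seq_len(n) - 1) * dt

  cyc <- resp$flush_s + resp$closed_s
  n_cyc <- ceiling(duration_h * 3600 / cyc)
  starts <- (seq_len(2L * n_cyc) - 1L)
  ph_start <- rep(c(0, resp$flush_s), n_cyc) +
    rep((seq_len(n_cyc) - 1L) * cyc, each = 2L)
  ph_end <- ph_start + rep(c(resp$flush_s, resp$closed_s), n_cyc)
  ph_lab <- rep(c("flush", "closed"), n_cyc)
  keep <- ph_start < duration_h * 3600
  phases <- data.frame(start_s = ph_start[keep], end_s = ph_end[keep],
                       phase = ph_lab[keep], stringsAsFactors = FALSE)
  phase_of <- ph_lab[pmin(findInterval(t, ph_start), length(ph_lab))]

  with_local_seed(seed, {
    n_min <- ceiling(duration_h * 60)
    act <- if (activity && state$params$activity_multiplier > 1) {
      simulate_activity(n_min, state$params$p_active_per_min,
                        state$params$p_rest_per_min)
    } else rep(FALSE, n_min)
    mult <- ifelse(act[pmin(floor(t / 60) + 1L, n_min)],
                   state$params$activity_multiplier, 1)
    uptake <- rest * mult                       # mg O2 / kg / h
    c_per_s <- (uptake * state$mass_kg + background_mg_h) / v_eff / 3600
    do <- integrate_do(t, c_per_s, phase_of, dt, sat,
                       flush_k = 3 / max(resp$flush_s, dt))
    obs <- if (noise_sd > 0) pmax(do + stats::rnorm(n, 0, noise_sd), 0) else do
    do_trace(
      samples = data.frame(time_s = t, do_mg_l = obs, temp_c = temp),
      phases = phases,
      chamber_id = sprintf("sim_seed%d", as.integer(seed %% 2147483647)),
      meta = list(sample_interval_s = dt, day = day, temp_c = temp,
                  true_resting_rate = rest, active_minutes = sum(act),
                  background_mg_h = background_mg_h, noise_sd = noise_sd,
                  v_eff_l = v_eff))
  })
}

#' Simulate an empty-chamber (background) trace
#'
#' Companion trace to [simulate_do_trace()]: the same cycle structure with no
#' fish, only a constant microbial background consumption, for background slope
#' estimation.
#'
#' @inheritParams simulate_do_trace
#' @param resp a [respirometer_config()] (its fish mass is ignored).
#' @param temp_c water temperature, degrees C.
#' @return A [do_trace()].
#' @export
simulate_background_trace <- function(resp, duration_h = 24, temp_c = 8,
                                      background_mg_h = 0.5, noise_sd = 0.01,
                                      seed = 1L, sample_dt_s = 5) {
  empty <- resp
  empty$fish_mass_kg <- 0
  params <- metabolic_params()
  st <- fish_state(params, mass_kg = 1e-9,
                   temp_schedule = data.frame(day = 0, temp_c = temp_c),
                   feeding = "fed", rng_seed = as.integer(seed %% 2147483647))
  empty$fish_mass_kg <- st$mass_kg
  tr <- simulate_do_trace(st, empty, duration_h = duration_h, day = 0,
                          noise_sd = noise_sd, seed = seed,
                          sample_dt_s = sample_dt_s,
                          background_mg_h = background_mg_h, activity = FALSE)
  tr$chamber_id <- sprintf("background_seed%d", as.integer(seed %% 2147483647))
  tr$meta$true_resting_rate <- 0
  tr
}

#' Simulate a post-chase recovery trace
#'
#' Emulates the manual intermittent procedure used to capture maximum oxygen
#' uptake: the fish enters the chamber at `mmr_ref`, uptake decays
#' exponentially (time constant `recovery_tau_min`) towards resting, the
#' chamber stays sealed until DO has fallen by `initial_drop_mg_l`, and is then
#' cycled with short flushes (DO up ~0.5 mg/l) and seals (DO down ~0.5 mg/l).
#' The steepest short-window slope therefore occurs in the first seconds of
#' the first closed segment.
#'
#' @inheritParams simulate_do_trace
#' @param initial_drop_mg_l DO drop allowed during the first sealed period.
#' @param reflush_rise_mg_l,reflush_drop_mg_l DO excursions of the subsequent
#'   manual flush/seal cycles.
#' @return A [do_trace()] with `meta$true_mmr` recording the ground truth.
#' @export
simulate_chase_recovery <- function(state, resp, day = 90,
                                    seed = state$rng_seed, duration_h = 1,
                                    noise_sd = 0, sample_dt_s = 1,
                                    background_mg_h = 0,
                                    initial_drop_mg_l = 2,
                                    reflush_rise_mg_l = 0.5,
                                    reflush_drop_mg_l = 0.5) {
  stopifnot(inherits(state, "fish_state"),
            inherits(resp, "respirometer_config"))
  if (abs(resp$fish_mass_kg - state$mass_kg) > 1e-12) {
    resp$fish_mass_kg <- state$mass_kg
  }
  v_eff <- effective_volume(resp)
  p <- state$params
  sched <- state$temp_schedule
  temp <- sched$temp_c[findInterval(day, sched$day)]
  sat <- do_saturation(temp)
  rest <- true_resting_rate(state, day)

  dt <- sample_dt_s
  n <- floor(duration_h * 3600 / dt)
  t <- (seq_len(n) - 1) * dt
  uptake <- rest + (p$mmr_ref - rest) * exp(-(t / 60) / p$recovery_tau_min)
  c_per_s <- (uptake * state$mass_kg + background_mg_h) / v_eff / 3600
  flush_k <- 3 / max(resp$flush_s, dt)

  do <- numeric(n)
  phase <- character(n)
  do[1L] <- sat
  cur <- "closed"
  anchor <- sat       # DO at the start of the current phase
  first_seal <- TRUE
  for (i in seq_len(n)) {
    phase[i] <- cur
    if (i == n) break
    if (cur == "closed") {
      do[i + 1L] <- do[i] - c_per_s[i] * dt
      lim <- if (first_seal) initial_drop_mg_l else reflush_drop_mg_l
      if (anchor - do[i + 1L] >= lim) {
        cur <- "flush"; anchor <- do[i + 1L]; first_seal <- FALSE
      }
    } else {
      s_star <- sat - c_per_s[i] / flush_k
      do[i + 1L] <- s_star + (do[i] - s_star) * exp(-flush_k * dt)
      if (do[i + 1L] - anchor >= reflush_rise_mg_l || do[i + 1L] >= sat - 1e-6) {
        cur <- "closed"; anchor <- do[i + 1L]
      }
    }
  }
  r <- rle(phase)
  ends <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends, -1L) + 1L)
  phases <- data.frame(start_s = t[starts_i],
                       end_s = c(t[starts_i[-1L]], t[n] + dt),
                       phase = r$values, stringsAsFactors = FALSE)
  obs <- with_local_seed(seed, {
    if (noise_sd > 0) pmax(do + stats::rnorm(n, 0, noise_sd), 0) else do
  })
  do_trace(
    samples = data.frame(time_s = t, do_mg_l = obs, temp_c = temp),
    phases = phases,
    chamber_id = sprintf("chase_seed%d", as.integer(seed %% 2147483647)),
    meta = list(sample_interval_s = dt, day = day, temp_c = temp,
                chase = TRUE, true_mmr = p$mmr_ref,
                true_resting_rate = rest, background_mg_h = background_mg_h,
                noise_sd = noise_sd, v_eff_l = v_eff))
}

#' Simulate method for fish states
#'
#' Convenience wrapper: `simulate()` on a [fish_state()] produces `nsim`
#' respirometry traces via [simulate_do_trace()].
#'
#' @param object a [fish_state()].
#' @param nsim number of traces.
#' @param seed base seed; trace `i` uses `seed + i - 1`.
#' @param ... passed to [simulate_do_trace()] (`resp` is required).
#' @return A list of [do_trace()] objects (a single trace if `nsim = 1`).
#' @export
simulate.fish_state <- function(object, nsim = 1, seed = object$rng_seed, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_do_trace(object, seed = seed + i - 1L, ...)
  })
  if (nsim == 1L) out[[1L]] else out
}
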