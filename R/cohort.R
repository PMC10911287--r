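#' Describe a cold-by-feeding acclimation experiment
#'
#' The design object behind [simulate_cohort()] and [run_pipeline()]: a
#' full-factorial temperature-by-feeding layout with repeated measurement days
#' and the generating parameters for body and organ trajectories. Defaults
#' emulate a 90-day experiment on ~140-g salmonids held at 2 or 8 degrees C,
#' fed a 0.5% body-mass ration or starved, measured at days 0/30/60/90:
#' fed fish grow slowly and keep (or gain) condition, starved fish lose mass
#' and fat and gain moisture, and at dissection the digestive organs of
#' starved fish are atrophied (default -40%) while the ventricle is spared.
#'
#' @param n_per_group fish per treatment group.
#' @param temps acclimation temperatures, degrees C.
#' @param feeding feeding treatments.
#' @param days measurement days (non-decreasing).
#' @param params a [metabolic_params()] shared by all fish.
#' @param mass0_mean_g,mass0_cv initial body mass distribution (lognormal).
#' @param k0_mean,k0_sd initial Fulton condition factor, used to derive
#'   standard length from mass.
#' @param sgr_fed,sgr_starved,sgr_sd specific growth rates (% day^-1) by
#'   feeding treatment, with between-fish SD.
#' @param fat0,fat_fed_end,fat_starved_end body-fat fraction at day 0 and at
#'   the final day by treatment (linear in between).
#' @param moisture0,moisture_starved_end moisture fraction at day 0 and the
#'   starved endpoint.
#' @param organ_frac named fractions of body mass for each organ at the
#'   reference condition.
#' @param starved_organ_mult named multiplicative organ-size offsets applied
#'   to starved fish at dissection (0.6 = 40% atrophy).
#' @param organ_allometry_b allometric exponent of organ mass on body mass.
#' @param organ_noise_cv lognormal CV of individual organ masses.
#' @param tg_conc,protein_conc,ks named lists (`fed`, `starved`) of per-organ
#'   triglyceride concentration (g/g), protein concentration (g/g) and
#'   fractional protein-synthesis rate (% day^-1) at dissection.
#' @param conc_noise_cv lognormal CV for concentrations and Ks.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 8, temps = c(2, 8),
                          feeding = c("fed", "starved"),
                          days = c(0, 30, 60, 90),
                          params = metabolic_params(),
                          mass0_mean_g = 137.78, mass0_cv = 0.15,
                          k0_mean = 1.40, k0_sd = 0.08,
                          sgr_fed = 0.20, sgr_starved = -0.12, sgr_sd = 0.05,
                          fat0 = 0.09, fat_fed_end = 0.10,
                          fat_starved_end = 0.03,
                          moisture0 = 0.72, moisture_starved_end = 0.78,
                          organ_frac = c(ventricle = 0.0010, liver = 0.012,
                                         stomach = 0.008, pylorus = 0.007,
                                         intestine = 0.009),
                          starved_organ_mult = c(ventricle = 1.0, liver = 0.65,
                                                 stomach = 0.60, pylorus = 0.60,
                                                 intestine = 0.60),
                          organ_allometry_b = 0.9, organ_noise_cv = 0.10,
                          tg_conc = list(fed = c(liver = 0.060, total_gut = 0.050,
                                                 white_muscle = 0.020),
                                         starved = c(liver = 0.020,
                                                     total_gut = 0.015,
                                                     white_muscle = 0.005)),
                          protein_conc = list(fed = c(liver = 0.16,
                                                      total_gut = 0.13,
                                                      white_muscle = 0.18),
                                              starved = c(liver = 0.15,
                                                          total_gut = 0.125,
                                                          white_muscle = 0.175)),
                          ks = list(fed = c(ventricle = 1.2, liver = 3.0,
                                            total_gut = 2.0, white_muscle = 0.4),
                                    starved = c(ventricle = 1.0, liver = 1.8,
                                                total_gut = 1.0,
                                                white_muscle = 0.25)),
                          conc_noise_cv = 0.10) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.unsorted(days)) stop("measurement days must be non-decreasing")
  stopifnot(inherits(params, "metabolic_params"))
  groups <- expand.grid(feeding = feeding, temp_c = temps,
                        stringsAsFactors = FALSE)
  groups$group <- sprintf("%s_%gC", groups$feeding, groups$temp_c)
  if (anyDuplicated(groups$group)) stop("group labels must be unique")
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 days = days, params = params,
                 mass0_mean_g = mass0_mean_g, mass0_cv = mass0_cv,
                 k0_mean = k0_mean, k0_sd = k0_sd,
                 sgr_fed = sgr_fed, sgr_starved = sgr_starved, sgr_sd = sgr_sd,
                 fat0 = fat0, fat_fed_end = fat_fed_end,
                 fat_starved_end = fat_starved_end,
                 moisture0 = moisture0,
                 moisture_starved_end = moisture_starved_end,
                 organ_frac = organ_frac,
                 starved_organ_mult = starved_organ_mult,
                 organ_allometry_b = organ_allometry_b,
                 organ_noise_cv = organ_noise_cv,
                 tg_conc = tg_conc, protein_conc = protein_conc, ks = ks,
                 conc_noise_cv = conc_noise_cv),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", nrow(x$groups), "groups x", x$n_per_group,
      "fish; days", paste(x$days, collapse = "/"), "\n")
  print(x$groups)
  invisible(x)
}

## lognormal multiplier with given CV (sdlog = sqrt(log(1 + cv^2)))
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdl^2 / 2, sdl)
}

#' Simulate a cohort of fish with known ground truth
#'
#' Draws individual fish for every treatment group and generates their body
#' records across measurement days and organ/tissue records at dissection
#' (final day), together with a per-fish [fish_state()] carrying the
#' metabolic ground truth used for trace simulation. Fed fish gain mass at
#' `sgr_fed` % day^-1 and hold body fat; starved fish lose mass, deplete fat,
#' gain moisture, and show atrophied digestive organs and reduced tissue
#' synthesis rates. Organ masses scale allometrically
#' (`organ ~ mass^organ_allometry_b`) so the residual-adjustment machinery has
#' real non-1:1 scaling to correct.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `cohort` with elements `fish` (one row per fish),
#'   `body` (fish x day), `organs` (dissection records incl. a `total_gut`
#'   row per fish), `states` (named list of [fish_state()]) and
#'   `design` (the generating truth).
#' @export
simulate_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  g <- design$groups
  n <- design$n_per_group
  with_local_seed(seed, {
    fish <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      data.frame(fish_id = sprintf("%s_f%02d", g$group[i], seq_len(n)),
                 group = g$group[i], temp_c = g$temp_c[i],
                 feeding = g$feeding[i], stringsAsFactors = FALSE)
    }))
    nf <- nrow(fish)
    fish$mass0_g <- design$mass0_mean_g * .lnoise(nf, design$mass0_cv)
    k0 <- pmax(stats::rnorm(nf, design$k0_mean, design$k0_sd), 0.8)
    fish$length0_mm <- (1e5 * fish$mass0_g / k0)^(1 / 3)
    sgr_mu <- ifelse(fish$feeding == "fed", design$sgr_fed, design$sgr_starved)
    fish$sgr_true <- stats::rnorm(nf, sgr_mu, design$sgr_sd)
    fish$rng_seed <- as.integer((seed + 7919L * seq_len(nf)) %% 2147483647L)

    d_end <- max(design$days)
    body <- do.call(rbind, lapply(design$days, function(d) {
      mass_g <- fish$mass0_g * exp(fish$sgr_true / 100 * d)
      grow <- pmax(mass_g / fish$mass0_g, 1)   # length never shrinks
      len <- fish$length0_mm * grow^(1 / 4)
      frac <- if (d_end > 0) d / d_end else 0
      fat_end <- ifelse(fish$feeding == "fed", design$fat_fed_end,
                        design$fat_starved_end)
      moist_end <- ifelse(fish$feeding == "fed", design$moisture0,
                          design$moisture_starved_end)
      data.frame(fish_id = fish$fish_id, group = fish$group, day = d,
                 mass_g = mass_g, standard_length_mm = len,
                 fat_frac = design$fat0 + frac * (fat_end - design$fat0),
                 moisture_frac = design$moisture0 +
                   frac * (moist_end - design$moisture0),
                 stringsAsFactors = FALSE)
    }))

    ## dissection: organ masses at the final day
    mass_end_kg <- fish$mass0_g * exp(fish$sgr_true / 100 * d_end) / 1000
    b <- design$organ_allometry_b
    organ_names <- names(design$organ_frac)
    organs <- do.call(rbind, lapply(organ_names, function(o) {
      a <- design$organ_frac[[o]] * 146 * 0.146^(-b)   # g at 0.146 kg
      mult <- ifelse(fish$feeding == "starved",
                     design$starved_organ_mult[[o]], 1)
      data.frame(fish_id = fish$fish_id, group = fish$group, organ = o,
                 organ_mass_g = a * mass_end_kg^b * mult *
                   .lnoise(nf, design$organ_noise_cv),
                 stringsAsFactors = FALSE)
    }))
    gut_parts <- c("stomach", "pylorus", "intestine")
    gut <- stats::aggregate(organ_mass_g ~ fish_id + group,
                            data = organs[organs$organ %in% gut_parts, ],
                            FUN = sum)
    gut$organ <- "total_gut"
    wm <- data.frame(fish_id = fish$fish_id, group = fish$group,
                     organ = "white_muscle", organ_mass_g = NA_real_,
                     stringsAsFactors = FALSE)
    organs <- rbind(organs, gut[names(organs)], wm)
    organs <- organs[order(organs$fish_id, organs$organ), ]
    row.names(organs) <- NULL

    len_end <- body$standard_length_mm[body$day == d_end]
    organs$intestine_length_mm <- NA_real_
    ii <- organs$organ == "intestine"
    int_mult <- ifelse(fish$feeding[match(organs$fish_id[ii], fish$fish_id)] ==
                         "starved", 0.92, 1)
    organs$intestine_length_mm[ii] <-
      1.05 * len_end[match(organs$fish_id[ii], fish$fish_id)] * int_mult *
      .lnoise(sum(ii), design$organ_noise_cv / 2)

    for (col in c("tg_conc", "protein_conc", "ks_pct_day")) {
      organs[[col]] <- NA_real_
    }
    spec_map <- list(tg_conc = design$tg_conc, protein_conc = design$protein_conc,
                     ks_pct_day = design$ks)
    feed_of <- fish$feeding[match(organs$fish_id, fish$fish_id)]
    for (col in names(spec_map)) {
      for (fd in c("fed", "starved")) {
        vals <- spec_map[[col]][[fd]]
        for (o in names(vals)) {
          sel <- organs$organ == o & feed_of == fd
          organs[[col]][sel] <- vals[[o]] *
            .lnoise(sum(sel), design$conc_noise_cv)
        }
      }
    }

    states <- lapply(seq_len(nf), function(i) {
      fish_state(design$params, mass_kg = fish$mass0_g[i] / 1000,
                 temp_schedule = data.frame(day = 0, temp_c = fish$temp_c[i]),
                 feeding = fish$feeding[i], rng_seed = fish$rng_seed[i])
    })
    names(states) <- fish$fish_id

    structure(list(fish = fish, body = body, organs = organs, states = states,
                   design = design, seed = as.integer(seed %% 2147483647L)),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$fish), "fish in", length(unique(x$fish$group)),
      "groups; body records at days",
      paste(unique(x$body$day), collapse = "/"), "\n")
  invisible(x)
}
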