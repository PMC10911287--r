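#' End-to-end experiment configuration
#'
#' Bundles the cohort design with the per-temperature respirometer settings
#' and the estimator parameters for a full pipeline run. The default
#' respirometer cycles follow the usual cold-water protocol: a 2-min flush
#' with a 10-min closed period and one 6-min slope window at 8 degrees C, and
#' a 22-min closed period with two 6-min windows at 2 degrees C (so both
#' temperatures yield a measurement every 12 min on average), always excluding
#' the first 4 min of each closed period.
#'
#' @param design a [cohort_design()].
#' @param resp_by_temp named list of [respirometer_config()] keyed by
#'   temperature (as character); defaults cover 2 and 8 degrees C.
#' @param quantile_p SMR quantile.
#' @param smr_method `"quantile"` or `"mean_below_p"`.
#' @param window_h SMR/average analysis window, hours.
#' @param trace_duration_h simulated trace length per fish-day, hours.
#' @param mmr_window_s MMR sliding-window length, seconds.
#' @param min_records minimum usable MO2 records per estimate.
#' @param r2_min QC threshold on window r2. Default 0 (disabled): at cold
#'   temperatures the true closed-phase decline is shallow relative to optode
#'   noise, so an absolute r2 gate would censor precisely the low-rate
#'   measurements the SMR quantile needs while retaining activity-elevated
#'   windows. Raise it only when noise is small relative to the slope signal.
#' @param noise_sd optode noise SD, mg O2 per litre.
#' @param sample_dt_s trace sampling interval, seconds.
#' @param chase_dt_s sampling interval of post-chase traces, seconds.
#' @param background_mg_h simulated chamber background respiration, mg O2/h
#'   (an empty-chamber trace is simulated and used for correction when > 0).
#' @param ref_mass_kg reference body mass for residual adjustment (non-final
#'   days).
#' @param ref_lean_mass_kg reference lean mass for final-day adjustment.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(design = cohort_design(),
                              resp_by_temp = NULL,
                              quantile_p = 0.20,
                              smr_method = c("quantile", "mean_below_p"),
                              window_h = 24, trace_duration_h = 24,
                              mmr_window_s = 90, min_records = 20,
                              r2_min = 0, noise_sd = 0.01,
                              sample_dt_s = 5, chase_dt_s = 1,
                              background_mg_h = 0,
                              ref_mass_kg = 0.146, ref_lean_mass_kg = 0.154) {
  smr_method <- match.arg(smr_method)
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(resp_by_temp)) {
    resp_by_temp <- list(
      "8" = respirometer_config(closed_s = 600, n_slopes_per_closed = 1L),
      "2" = respirometer_config(closed_s = 1320, n_slopes_per_closed = 2L))
  }
  for (tt in unique(design$groups$temp_c)) {
    if (!as.character(tt) %in% names(resp_by_temp)) {
      stop("no respirometer configuration for temperature ", tt)
    }
  }
  structure(list(design = design, resp_by_temp = resp_by_temp,
                 quantile_p = quantile_p, smr_method = smr_method,
                 window_h = window_h, trace_duration_h = trace_duration_h,
                 mmr_window_s = mmr_window_s, min_records = min_records,
                 r2_min = r2_min, noise_sd = noise_sd,
                 sample_dt_s = sample_dt_s, chase_dt_s = chase_dt_s,
                 background_mg_h = background_mg_h,
                 ref_mass_kg = ref_mass_kg,
                 ref_lean_mass_kg = ref_lean_mass_kg),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  print(x$design)
  cat(sprintf("  SMR: %s p=%.2f over final %g h; MMR window %g s; noise %g mg/l\n",
              x$smr_method, x$quantile_p, x$window_h, x$mmr_window_s,
              x$noise_sd))
  invisible(x)
}

.trace_seed <- function(seed, fish_i, day_i, kind = 0L) {
  as.integer((as.numeric(seed) * 1000003 + fish_i * 1009 + day_i * 101 +
                kind * 13) %% 2147483647)
}

.trace_file <- function(dir, fish_id, day, chase = FALSE) {
  file.path(dir, sprintf("%s_day%03d%s.csv", fish_id, day,
                         if (chase) "_chase" else ""))
}

#' Run the full respirometry-and-energetics pipeline
#'
#' Simulates (or ingests) a cohort experiment and carries every fish and
#' measurement day through slope extraction, SMR / average-MO2 estimation,
#' final-day MMR detection and aerobic scope, Q10 tables (between-temperature
#' within each feeding treatment at every day, the day-0 row being the acute
#' response), residual mass adjustment of SMR (to `ref_mass_kg`, or
#' `ref_lean_mass_kg` on the final day using fat-derived lean mass), and
#' starved-vs-fed percent contrasts at the final day. Missing or failed
#' fish-day estimates are recorded and the run continues.
#'
#' In `"simulate"` mode traces are generated from the cohort's ground-truth
#' states; with `out_dir` set, all tables (and with `write_traces = TRUE` the
#' traces themselves) are written, producing a bundle that `"ingest"` mode can
#' re-read and reproduce exactly.
#'
#' @param config an [experiment_config()].
#' @param mode `"simulate"` or `"ingest"`.
#' @param input_dir directory of a previously written bundle (ingest mode).
#' @param out_dir optional output directory for tables.
#' @param write_traces also write every trace CSV (simulate mode).
#' @param seed integer seed for the whole run.
#' @return An object of class `respirometry_run` with elements `summary`
#'   (per fish-day estimates), `q10_table`, `adjusted` (per-day group means at
#'   the reference mass), `contrasts` (starved vs fed, final day), `cohort`,
#'   `qc` and `manifest`.
#' @export
run_pipeline <- function(config, mode = c("simulate", "ingest"),
                         input_dir = NULL, out_dir = NULL,
                         write_traces = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "experiment_config"))
  design <- config$design
  if (mode == "ingest") {
    if (is.null(input_dir)) stop("ingest mode requires input_dir")
    cohort <- read_cohort(input_dir, design)
  } else {
    cohort <- simulate_cohort(design, seed = seed)
  }
  fish <- cohort$fish
  days <- design$days
  d_end <- max(days)
  trace_dir <- if (!is.null(out_dir)) file.path(out_dir, "traces") else NULL
  if (!is.null(trace_dir) && write_traces) {
    dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)
  }

  ## background traces: one per temperature per day index (shared clock)
  bg_of <- function(temp_c, day_i) {
    if (config$background_mg_h <= 0) return(NULL)
    simulate_background_trace(
      config$resp_by_temp[[as.character(temp_c)]],
      duration_h = config$trace_duration_h, temp_c = temp_c,
      background_mg_h = config$background_mg_h, noise_sd = config$noise_sd,
      seed = .trace_seed(seed, 0L, day_i, 9L), sample_dt_s = config$sample_dt_s)
  }

  rows <- list()
  qc_fail_total <- 0L
  missing <- character(0)
  for (di in seq_along(days)) {
    d <- days[di]
    bg_by_temp <- list()
    for (fi in seq_len(nrow(fish))) {
      f <- fish[fi, ]
      mass_kg <- cohort$body$mass_g[cohort$body$fish_id == f$fish_id &
                                      cohort$body$day == d] / 1000
      resp <- config$resp_by_temp[[as.character(f$temp_c)]]
      resp$fish_mass_kg <- mass_kg
      tkey <- as.character(f$temp_c)
      if (config$background_mg_h > 0 && is.null(bg_by_temp[[tkey]])) {
        bg_by_temp[[tkey]] <- bg_of(f$temp_c, di)
      }
      res <- tryCatch({
        tr <- if (mode == "ingest") {
          path <- .trace_file(file.path(input_dir, "traces"), f$fish_id, d)
          read_do_trace(path, phase_path = default_phase_path(path))
        } else {
          st <- cohort$states[[f$fish_id]]
          st$mass_kg <- mass_kg
          simulate_do_trace(st, resp, duration_h = config$trace_duration_h,
                            day = d, noise_sd = config$noise_sd,
                            seed = .trace_seed(seed, fi, di),
                            sample_dt_s = config$sample_dt_s,
                            background_mg_h = config$background_mg_h)
        }
        if (write_traces && !is.null(trace_dir) && mode == "simulate") {
          write_do_trace(tr, .trace_file(trace_dir, f$fish_id, d))
        }
        rec <- suppressMessages(
          extract_mo2(tr, resp, background = bg_by_temp[[tkey]],
                      fish_id = f$fish_id, r2_min = config$r2_min))
        smr <- estimate_smr(rec, window_h = config$window_h,
                            quantile_p = config$quantile_p,
                            method = config$smr_method,
                            min_records = config$min_records)
        avg <- estimate_average_mo2(rec, window_h = config$window_h,
                                    min_records = config$min_records)
        mmr <- NA_real_
        if (d == d_end) {
          ch <- if (mode == "ingest") {
            path <- .trace_file(file.path(input_dir, "traces"), f$fish_id, d,
                                chase = TRUE)
            read_do_trace(path, phase_path = default_phase_path(path))
          } else {
            st <- cohort$states[[f$fish_id]]
            st$mass_kg <- mass_kg
            simulate_chase_recovery(st, resp, day = d,
                                    seed = .trace_seed(seed, fi, di, 1L),
                                    noise_sd = config$noise_sd,
                                    sample_dt_s = config$chase_dt_s)
          }
          if (write_traces && !is.null(trace_dir) && mode == "simulate") {
            write_do_trace(ch, .trace_file(trace_dir, f$fish_id, d,
                                           chase = TRUE))
          }
          mmr <- detect_mmr(ch, resp, window_s = config$mmr_window_s)$mmr
        }
        list(rec = rec, smr = smr, avg = avg, mmr = mmr)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        missing <- c(missing, sprintf("%s day %g: %s", f$fish_id, d,
                                      conditionMessage(res)))
        rows[[length(rows) + 1L]] <- data.frame(
          fish_id = f$fish_id, group = f$group, temp_c = f$temp_c,
          feeding = f$feeding, day = d, mass_kg = mass_kg,
          smr = NA_real_, mo2_average = NA_real_, mmr = NA_real_,
          aas = NA_real_, n_used = 0L, n_qc_fail = 0L,
          stringsAsFactors = FALSE)
        next
      }
      qc_fail_total <- qc_fail_total + sum(!res$rec$qc_pass)
      rows[[length(rows) + 1L]] <- data.frame(
        fish_id = f$fish_id, group = f$group, temp_c = f$temp_c,
        feeding = f$feeding, day = d, mass_kg = mass_kg,
        smr = res$smr, mo2_average = res$avg, mmr = res$mmr,
        aas = if (is.na(res$mmr)) NA_real_ else
          aerobic_scope(res$smr, res$mmr),
        n_used = sum(res$rec$qc_pass), n_qc_fail = sum(!res$rec$qc_pass),
        stringsAsFactors = FALSE)
    }
  }
  summary_tab <- do.call(rbind, rows)

  q10_table <- .q10_table(summary_tab, design)
  adjusted <- .adjust_summary(summary_tab, cohort, config)
  contrasts <- .feeding_contrasts(adjusted, d_end)

  manifest <- list(
    package = "icresp",
    version = as.character(utils::packageVersion("icresp")),
    seed = as.integer(seed %% 2147483647), mode = mode,
    n_fish = nrow(fish), days = days,
    settings = list(quantile_p = config$quantile_p,
                    smr_method = config$smr_method,
                    window_h = config$window_h,
                    mmr_window_s = config$mmr_window_s,
                    noise_sd = config$noise_sd,
                    sample_dt_s = config$sample_dt_s,
                    background_mg_h = config$background_mg_h,
                    ref_mass_kg = config$ref_mass_kg,
                    ref_lean_mass_kg = config$ref_lean_mass_kg))

  bundle <- structure(
    list(summary = summary_tab, q10_table = q10_table, adjusted = adjusted,
         contrasts = contrasts, cohort = cohort,
         qc = list(n_qc_fail = qc_fail_total, missing = missing),
         manifest = manifest),
    class = "respirometry_run")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

## Q10 between the two temperatures, per feeding treatment and day
.q10_table <- function(summary_tab, design) {
  temps <- sort(unique(design$groups$temp_c))
  if (length(temps) != 2L) return(NULL)
  out <- list()
  for (fd in unique(design$groups$feeding)) {
    for (d in unique(summary_tab$day)) {
      sel <- summary_tab$feeding == fd & summary_tab$day == d &
        !is.na(summary_tab$smr)
      lo <- summary_tab$smr[sel & summary_tab$temp_c == temps[1L]]
      hi <- summary_tab$smr[sel & summary_tab$temp_c == temps[2L]]
      if (length(lo) == 0L || length(hi) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        feeding = fd, day = d, t1 = temps[1L], t2 = temps[2L],
        r1 = mean(lo), r2 = mean(hi),
        q10 = q10(mean(lo), mean(hi), temps[1L], temps[2L]),
        label = if (d == min(summary_tab$day)) "acute" else "acclimated",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## residual mass adjustment of SMR per day; lean mass on the final day
.adjust_summary <- function(summary_tab, cohort, config) {
  d_end <- max(cohort$design$days)
  out <- list()
  for (d in unique(summary_tab$day)) {
    s <- summary_tab[summary_tab$day == d & !is.na(summary_tab$smr), ,
                     drop = FALSE]
    if (nrow(s) < 3L) next
    use_lean <- d == d_end
    if (use_lean) {
      b <- cohort$body[cohort$body$day == d, ]
      fat <- b$fat_frac[match(s$fish_id, b$fish_id)]
      covar <- lean_mass(s$mass_kg, fat)
      ref <- config$ref_lean_mass_kg
    } else {
      covar <- s$mass_kg
      ref <- config$ref_mass_kg
    }
    fit <- suppressWarnings(
      mass_adjust(s$smr * s$mass_kg, covar, groups = s$group, ref = ref))
    adj <- adjusted(fit) / ref      # back to mass-specific at the reference
    grp <- tapply(adj, s$group, mean)
    out[[length(out) + 1L]] <- data.frame(
      day = d, group = names(grp), covariate = if (use_lean) "lean_mass"
      else "mass", ref_kg = ref, smr_adj = as.numeric(grp),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## starved vs fed percent difference of adjusted SMR at the final day
.feeding_contrasts <- function(adjusted, d_end) {
  if (is.null(adjusted)) return(NULL)
  a <- adjusted[adjusted$day == d_end, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  parts <- do.call(rbind, strsplit(a$group, "_"))
  a$feeding <- parts[, 1L]
  a$temp <- parts[, 2L]
  out <- list()
  for (tt in unique(a$temp)) {
    fed <- a$smr_adj[a$feeding == "fed" & a$temp == tt]
    st <- a$smr_adj[a$feeding == "starved" & a$temp == tt]
    if (length(fed) == 1L && length(st) == 1L) {
      out[[length(out) + 1L]] <- data.frame(
        day = d_end, temp = tt, fed_adj = fed, starved_adj = st,
        pct_diff = 100 * (st - fed) / fed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## ---- bundle I/O -----------------------------------------------------------

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible())
    out <- df
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(out[num], .fmt_num)
    utils::write.csv(out, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wr(bundle$summary, "summary.csv")
  wr(bundle$q10_table, "q10.csv")
  wr(bundle$adjusted, "adjusted.csv")
  wr(bundle$contrasts, "contrasts.csv")
  wr(bundle$cohort$fish, "fish.csv")
  wr(bundle$cohort$body, "cohort_body.csv")
  wr(bundle$cohort$organs, "cohort_organs.csv")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

## rebuild a cohort object from a written bundle (ingest mode)
read_cohort <- function(input_dir, design) {
  fish <- utils::read.csv(file.path(input_dir, "fish.csv"),
                          stringsAsFactors = FALSE)
  body <- utils::read.csv(file.path(input_dir, "cohort_body.csv"),
                          stringsAsFactors = FALSE)
  organs_path <- file.path(input_dir, "cohort_organs.csv")
  organs <- if (file.exists(organs_path)) {
    utils::read.csv(organs_path, stringsAsFactors = FALSE)
  } else NULL
  states <- lapply(seq_len(nrow(fish)), function(i) {
    fish_state(design$params, mass_kg = fish$mass0_g[i] / 1000,
               temp_schedule = data.frame(day = 0, temp_c = fish$temp_c[i]),
               feeding = fish$feeding[i], rng_seed = fish$rng_seed[i])
  })
  names(states) <- fish$fish_id
  structure(list(fish = fish, body = body, organs = organs, states = states,
                 design = design, seed = NA_integer_),
            class = "cohort")
}

#' @export
print.respirometry_run <- function(x, ...) {
  cat("<respirometry_run>", nrow(x$summary), "fish-day estimates;",
      x$qc$n_qc_fail, "QC-flagged records;",
      length(x$qc$missing), "missing\n")
  cat("  use report() for the full summary\n")
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Prints group-level SMR trajectories, the Q10 table, the final-day
#' starved-vs-fed contrasts and QC counts. Every number shown is a cell of
#' the bundle's tables.
#'
#' @param bundle a `respirometry_run` from [run_pipeline()].
#' @return The bundle, invisibly.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "respirometry_run"))
  s <- bundle$summary
  cat("== Respirometry pipeline report ==\n\n")
  cat("Group mean SMR (mg O2/kg/h) by day:\n")
  tab <- tapply(s$smr, list(s$group, s$day), mean, na.rm = TRUE)
  print(round(tab, 2))
  cat("\nGroup mean average MO2 (mg O2/kg/h) by day:\n")
  print(round(tapply(s$mo2_average, list(s$group, s$day), mean, na.rm = TRUE), 2))
  if (any(!is.na(s$mmr))) {
    cat("\nFinal-day MMR / AAS (group means, mg O2/kg/h):\n")
    fin <- s[!is.na(s$mmr), ]
    print(round(cbind(mmr = tapply(fin$mmr, fin$group, mean),
                      aas = tapply(fin$aas, fin$group, mean)), 2))
  }
  if (!is.null(bundle$q10_table)) {
    cat("\nThermal sensitivity (Q10 of group-mean SMR between temperatures):\n")
    q <- bundle$q10_table
    print(data.frame(feeding = q$feeding, day = q$day, label = q$label,
                     q10 = round(q$q10, 2)), row.names = FALSE)
  }
  if (!is.null(bundle$contrasts)) {
    cat("\nStarved vs fed, final day (SMR adjusted to reference lean mass):\n")
    print(data.frame(temp = bundle$contrasts$temp,
                     pct_diff = round(bundle$contrasts$pct_diff, 1)),
          row.names = FALSE)
  }
  cat(sprintf("\nQC: %d flagged slope record(s); %d missing fish-day estimate(s)\n",
              bundle$qc$n_qc_fail, length(bundle$qc$missing)))
  if (length(bundle$qc$missing) > 0L) {
    cat("  ", paste(bundle$qc$missing, collapse = "\n  "), "\n")
  }
  invisible(bundle)
}
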