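#' Segment a trace into slope-fitting windows
#'
#' For each closed phase of the trace, drops the first `exclusion_s` seconds
#' (mixing/adjustment after the flush) and lays down `n_slopes_per_closed`
#' consecutive, non-overlapping windows of `slope_window_s` seconds starting at
#' the exclusion boundary. Closed phases too short for even one window yield no
#' windows and a warning. With a typical 10-min closed period, 4-min exclusion
#' and one 6-min window this gives `[240, 600)` s within each closed phase;
#' with a 22-min closed period and two windows, `[240, 600)` and `[600, 960)`.
#'
#' @param trace a [do_trace()] with phase marks (use [infer_phases()] first if
#'   the logger recorded none).
#' @param resp a [respirometer_config()].
#' @return data.frame with one row per window: `cycle` (closed-phase index),
#'   `slope_index` (window index within the phase), `start_s`, `end_s`
#'   (absolute trace time, half-open).
#' @export
segment_cycles <- function(trace, resp) {
  stopifnot(inherits(trace, "do_trace"), inherits(resp, "respirometer_config"))
  p <- trace$phases
  closed <- p[p$phase == "closed", , drop = FALSE]
  empty <- data.frame(cycle = integer(0), slope_index = integer(0),
                      start_s = numeric(0), end_s = numeric(0))
  if (nrow(closed) == 0L) {
    warning("trace has no closed phases; no slope windows produced")
    return(empty)
  }
  closed <- closed[order(closed$start_s), , drop = FALSE]
  out <- vector("list", nrow(closed))
  n_short <- 0L
  for (i in seq_len(nrow(closed))) {
    len <- closed$end_s[i] - closed$start_s[i]
    n_fit <- floor((len - resp$exclusion_s) / resp$slope_window_s)
    n_win <- max(0L, min(resp$n_slopes_per_closed, n_fit))
    if (n_win < 1L) {
      n_short <- n_short + 1L
      next
    }
    k <- seq_len(n_win) - 1L
    out[[i]] <- data.frame(
      cycle = i, slope_index = k + 1L,
      start_s = closed$start_s[i] + resp$exclusion_s + k * resp$slope_window_s,
      end_s = closed$start_s[i] + resp$exclusion_s +
        (k + 1L) * resp$slope_window_s)
  }
  if (n_short > 0L) {
    warning(n_short, " closed phase(s) shorter than exclusion_s + slope_window_s",
            " yielded no windows")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

## stable OLS on centered time; returns slope (per second), r2, n
.ols_slope <- function(t, y) {
  n <- length(t)
  if (n < 3L) return(list(slope = NA_real_, r2 = NA_real_, n = n))
  tc <- t - mean(t)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  syy <- sum(yc^2)
  if (sxx == 0) return(list(slope = NA_real_, r2 = NA_real_, n = n))
  sxy <- sum(tc * yc)
  slope <- sxy / sxx
  r2 <- if (syy > 0) (sxy * sxy) / (sxx * syy) else NA_real_
  list(slope = slope, r2 = r2, n = n)
}

#' Fit the DO decline slope in one window
#'
#' Ordinary least-squares regression of dissolved oxygen on time over the
#' samples with `time_s` in `[start_s, end_s)`. The slope is reported per hour
#' (mg O2 l^-1 h^-1; negative while the animal consumes oxygen). Windows with
#' fewer than 3 samples, or with constant DO (undefined r2), are returned with
#' a QC failure reason rather than an error.
#'
#' @param trace a [do_trace()].
#' @param window numeric length-2, `c(start_s, end_s)`.
#' @return list with `slope` (mg/l/h), `r2`, `n`, `qc_pass`, `qc_reason`.
#' @export
fit_window_slope <- function(trace, window) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  s <- trace$samples
  sel <- s$time_s >= window[1L] & s$time_s < window[2L]
  fit <- .ols_slope(s$time_s[sel], s$do_mg_l[sel])
  if (fit$n < 3L) {
    return(list(slope = NA_real_, r2 = NA_real_, n = fit$n, qc_pass = FALSE,
                qc_reason = sprintf("only %d sample(s) in window", fit$n)))
  }
  if (is.na(fit$r2)) {
    ## constant DO: slope 0 but no variance to explain
    return(list(slope = 0, r2 = NA_real_, n = fit$n, qc_pass = FALSE,
                qc_reason = "zero DO variance in window"))
  }
  list(slope = fit$slope * 3600, r2 = fit$r2, n = fit$n, qc_pass = TRUE,
       qc_reason = NA_character_)
}

#' Subtract background respiration from a DO slope
#'
#' Microbial oxygen consumption in the chamber shows up as a (small, usually
#' negative) slope in a time-matched empty-chamber trace; subtracting it
#' isolates the fish's uptake.
#'
#' @param slope fish-chamber DO slope, mg O2 l^-1 h^-1.
#' @param background_slope matched empty-chamber slope in the same units, or
#'   `NA`/`NULL` when no background was recorded (slope passes through
#'   unchanged with a warning).
#' @return list with `slope` (corrected) and `background_corrected` flag.
#' @export
background_correct <- function(slope, background_slope = NULL) {
  if (is.null(background_slope) || length(background_slope) == 0L ||
      is.na(background_slope)) {
    warning("no background slope supplied; slope left uncorrected")
    return(list(slope = slope, background_corrected = FALSE))
  }
  list(slope = slope - background_slope, background_corrected = TRUE)
}

#' Convert a corrected DO slope to oxygen uptake
#'
#' `MO2_abs = -slope * V_eff` with `V_eff = volume_l - fish_mass_kg / density`
#' (the fish displaces water); the mass-specific rate divides by body mass.
#' A positive corrected slope (apparent oxygen production) yields a negative
#' uptake and should be flagged by the caller.
#'
#' @param corrected_slope background-corrected DO slope, mg O2 l^-1 h^-1.
#' @param resp a [respirometer_config()] with a positive fish mass.
#' @return list with `mo2_abs_mg_h` and `mo2_mgkg_h`.
#' @export
slope_to_mo2 <- function(corrected_slope, resp) {
  v_eff <- effective_volume(resp)
  if (resp$fish_mass_kg <= 0) stop("fish_mass_kg must be positive for MO2")
  mo2_abs <- -corrected_slope * v_eff
  list(mo2_abs_mg_h = mo2_abs, mo2_mgkg_h = mo2_abs / resp$fish_mass_kg)
}

## background slopes table from an empty-chamber trace: one slope per window
background_slopes <- function(background, resp) {
  win <- suppressWarnings(segment_cycles(background, resp))
  if (nrow(win) == 0L) return(win)
  win$slope <- NA_real_
  for (i in seq_len(nrow(win))) {
    f <- fit_window_slope(background, c(win$start_s[i], win$end_s[i]))
    win$slope[i] <- if (isTRUE(f$qc_pass)) f$slope else NA_real_
  }
  win$t_mid_s <- (win$start_s + win$end_s) / 2
  win[!is.na(win$slope), , drop = FALSE]
}

## nearest-in-time background slope for a window midpoint
match_background <- function(t_mid, bg_tab) {
  if (is.null(bg_tab) || nrow(bg_tab) == 0L) return(NA_real_)
  bg_tab$slope[which.min(abs(bg_tab$t_mid_s - t_mid))]
}

#' Extract oxygen-uptake measurements from a trace
#'
#' The full closed-phase workflow: segment the trace into slope windows
#' ([segment_cycles()]), fit each window ([fit_window_slope()]), subtract the
#' nearest-in-time background slope when an empty-chamber trace is supplied
#' ([background_correct()]), and convert to absolute and mass-specific uptake
#' ([slope_to_mo2()]). Records failing quality control (low r2, too few
#' samples, positive corrected slope) are retained and flagged, never silently
#' dropped; estimators downstream exclude them by default.
#'
#' @param trace a [do_trace()] with phase marks.
#' @param resp a [respirometer_config()].
#' @param background optional empty-chamber [do_trace()] recorded alongside, or
#'   a single numeric background slope (mg O2 l^-1 h^-1) applied to every
#'   window.
#' @param fish_id identifier copied into the output.
#' @param r2_min minimum r2 for a record to pass QC.
#' @return A data.frame of class `mo2_records`, one row per window:
#'   `fish_id, cycle, slope_index, window_start_s, window_end_s, t_mid_s,
#'   slope_do, r2, n, mo2_abs_mg_h, mo2_mgkg_h, background_corrected, qc_pass,
#'   qc_reason`.
#' @export
extract_mo2 <- function(trace, resp, background = NULL, fish_id = trace$chamber_id,
                        r2_min = 0.9) {
  win <- segment_cycles(trace, resp)
  bg_tab <- NULL
  bg_const <- NA_real_
  if (inherits(background, "do_trace")) {
    bg_resp <- resp
    bg_resp$fish_mass_kg <- 0
    bg_tab <- background_slopes(background, bg_resp)
  } else if (is.numeric(background) && length(background) == 1L) {
    bg_const <- background
  }
  n <- nrow(win)
  rec <- data.frame(
    fish_id = rep(as.character(fish_id), n), cycle = win$cycle,
    slope_index = win$slope_index, window_start_s = win$start_s,
    window_end_s = win$end_s, t_mid_s = (win$start_s + win$end_s) / 2,
    slope_do = NA_real_, r2 = NA_real_, n = NA_integer_,
    mo2_abs_mg_h = NA_real_, mo2_mgkg_h = NA_real_,
    background_corrected = FALSE, qc_pass = FALSE,
    qc_reason = NA_character_, stringsAsFactors = FALSE)
  have_bg <- !is.null(bg_tab) || !is.na(bg_const)
  for (i in seq_len(n)) {
    f <- fit_window_slope(trace, c(win$start_s[i], win$end_s[i]))
    rec$r2[i] <- f$r2
    rec$n[i] <- f$n
    if (!isTRUE(f$qc_pass)) {
      rec$slope_do[i] <- f$slope
      rec$qc_reason[i] <- f$qc_reason
      next
    }
    bg <- if (!is.na(bg_const)) bg_const else
      if (!is.null(bg_tab)) match_background(rec$t_mid_s[i], bg_tab) else NA_real_
    corr <- if (have_bg && !is.na(bg)) {
      list(slope = f$slope - bg, background_corrected = TRUE)
    } else {
      list(slope = f$slope, background_corrected = FALSE)
    }
    rec$slope_do[i] <- corr$slope
    rec$background_corrected[i] <- corr$background_corrected
    mo2 <- slope_to_mo2(corr$slope, resp)
    rec$mo2_abs_mg_h[i] <- mo2$mo2_abs_mg_h
    rec$mo2_mgkg_h[i] <- mo2$mo2_mgkg_h
    if (corr$slope > 0) {
      rec$qc_pass[i] <- FALSE
      rec$qc_reason[i] <- "positive corrected slope"
    } else if (!is.na(f$r2) && f$r2 < r2_min) {
      rec$qc_pass[i] <- FALSE
      rec$qc_reason[i] <- sprintf("r2 %.3f below %.3f", f$r2, r2_min)
    } else {
      rec$qc_pass[i] <- TRUE
    }
  }
  n_fail <- sum(!rec$qc_pass)
  if (n_fail > 0L) {
    message(n_fail, " of ", n, " MO2 record(s) flagged by QC")
  }
  structure(rec, class = c("mo2_records", "data.frame"),
            fish_mass_kg = resp$fish_mass_kg)
}

#' @export
print.mo2_records <- function(x, ...) {
  cat(sprintf("<mo2_records> %d measurement(s), %d QC-passed\n",
              nrow(x), sum(x$qc_pass)))
  ok <- x$mo2_mgkg_h[x$qc_pass]
  if (length(ok) > 0L) {
    cat(sprintf("  mass-specific MO2: median %.2f [%.2f, %.2f] mg O2/kg/h\n",
                stats::median(ok), min(ok), max(ok)))
  }
  invisible(x)
}

#' Write / read an MO2 record table
#'
#' CSV round trip of the [extract_mo2()] output at full numeric precision.
#'
#' @param records an `mo2_records` data.frame.
#' @param path CSV path.
#' @return `path` (write) or the records (read).
#' @export
write_mo2_records <- function(records, path) {
  out <- records
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], .fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mo2_records
#' @export
read_mo2_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$qc_pass <- as.logical(rec$qc_pass)
  rec$background_corrected <- as.logical(rec$background_corrected)
  structure(rec, class = c("mo2_records", "data.frame"))
}
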