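#' @keywords internal
"_PACKAGE"

PHASE_LEVELS <- c("flush", "closed", "chase_recovery", "adjustment")

#' Construct a dissolved-oxygen trace
#'
#' A `do_trace` holds the time-stamped dissolved-oxygen record of one
#' respirometry chamber, together with the phase structure (flush / closed /
#' chase_recovery / adjustment intervals) that segmentation and slope fitting
#' rely on. Time is stored as seconds from trace start; phase intervals are
#' half-open `[start_s, end_s)`, so a sample sitting exactly on a boundary
#' belongs to the later interval.
#'
#' @param samples data.frame with columns `time_s` (strictly increasing),
#'   `do_mg_l` (dissolved oxygen, mg O2 per litre, non-negative) and `temp_c`
#'   (water temperature, degrees C).
#' @param phases data.frame with columns `start_s`, `end_s`, `phase`
#'   (one of `r paste(PHASE_LEVELS, collapse = ", ")`), or `NULL` for an
#'   unsegmented trace. Intervals must not overlap.
#' @param chamber_id chamber identifier (one chamber per trace).
#' @param meta named list of free-form metadata (e.g. sampling interval,
#'   wall-clock start, simulator ground truth).
#' @return An object of class `do_trace`.
#' @examples
#' tr <- do_trace(
#'   samples = data.frame(time_s = 0:5, do_mg_l = 9.5 - 0.01 * (0:5), temp_c = 8),
#'   phases = data.frame(start_s = 0, end_s = 6, phase = "closed")
#' )
#' tr
#' @export
do_trace <- function(samples, phases = NULL, chamber_id = "chamber1",
                     meta = list()) {
  stopifnot(is.data.frame(samples))
  need <- c("time_s", "do_mg_l", "temp_c")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("trace samples are missing column(s): ", paste(miss, collapse = ", "))
  }
  samples <- samples[need]
  samples[] <- lapply(samples, as.numeric)
  if (!is.null(phases)) {
    pneed <- c("start_s", "end_s", "phase")
    pmiss <- setdiff(pneed, names(phases))
    if (length(pmiss) > 0L) {
      stop("phase table is missing column(s): ", paste(pmiss, collapse = ", "))
    }
    phases <- phases[pneed]
    phases$start_s <- as.numeric(phases$start_s)
    phases$end_s <- as.numeric(phases$end_s)
    phases$phase <- as.character(phases$phase)
  } else {
    phases <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         phase = character(0))
  }
  obj <- structure(
    list(chamber_id = as.character(chamber_id), samples = samples,
         phases = phases, meta = meta),
    class = "do_trace")
  validate_do_trace(obj)
  obj
}

#' Validate a dissolved-oxygen trace
#'
#' Checks every structural invariant of a [do_trace()]: strictly increasing
#' time, non-negative oxygen, known phase labels, positive-length and
#' non-overlapping phase intervals. Errors name the violated invariant and
#' (for monotonicity) the first offending row.
#'
#' @param trace a `do_trace`.
#' @return `trace`, invisibly, if valid.
#' @export
validate_do_trace <- function(trace) {
  s <- trace$samples
  if (nrow(s) > 1L) {
    bad <- which(diff(s$time_s) <= 0)
    if (length(bad) > 0L) {
      stop("trace time must be strictly increasing; first violation at row ",
           bad[1L] + 1L)
    }
  }
  if (anyNA(s$time_s) || anyNA(s$do_mg_l)) {
    stop("trace samples contain missing time or DO values")
  }
  if (any(s$do_mg_l < 0)) {
    stop("dissolved oxygen must be non-negative; first violation at row ",
         which(s$do_mg_l < 0)[1L])
  }
  p <- trace$phases
  if (nrow(p) > 0L) {
    if (!all(p$phase %in% PHASE_LEVELS)) {
      stop("unknown phase label(s): ",
           paste(unique(p$phase[!p$phase %in% PHASE_LEVELS]), collapse = ", "))
    }
    if (any(p$end_s <= p$start_s)) {
      stop("phase intervals must have end_s > start_s")
    }
    o <- order(p$start_s)
    ps <- p[o, , drop = FALSE]
    if (nrow(ps) > 1L && any(ps$start_s[-1L] < ps$end_s[-nrow(ps)])) {
      stop("phase intervals must not overlap")
    }
  }
  invisible(trace)
}

#' @export
print.do_trace <- function(x, ...) {
  s <- x$samples
  cat("<do_trace> chamber", x$chamber_id, "\n")
  cat(sprintf("  %d samples spanning %.1f s", nrow(s),
              if (nrow(s) > 0L) diff(range(s$time_s)) else 0))
  if (nrow(s) > 1L) {
    cat(sprintf(" (median interval %.3g s)", stats::median(diff(s$time_s))))
  }
  cat("\n")
  if (nrow(x$phases) > 0L) {
    tab <- table(x$phases$phase)
    cat("  phases:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
        "\n")
  } else {
    cat("  phases: none recorded\n")
  }
  if (nrow(s) > 0L) {
    cat(sprintf("  DO range %.3f-%.3f mg/l, temp %.2f-%.2f C\n",
                min(s$do_mg_l), max(s$do_mg_l), min(s$temp_c), max(s$temp_c)))
  }
  invisible(x)
}

#' @export
plot.do_trace <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$time_s / 60, s$do_mg_l, type = "l",
                 xlab = "time (min)", ylab = expression(DO~(mg~l^-1)),
                 main = paste("chamber", x$chamber_id), ...)
  p <- x$phases
  closed <- p[p$phase == "closed", , drop = FALSE]
  if (nrow(closed) > 0L) {
    usr <- graphics::par("usr")
    graphics::rect(closed$start_s / 60, usr[3], closed$end_s / 60, usr[4],
                   col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  }
  invisible(x)
}

## full-precision number formatting so write -> read round-trips doubles exactly
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = 1)
  out[is.na(x)] <- "NA"
  gsub(" ", "", out)
}

#' Read a dissolved-oxygen trace from CSV
#'
#' Reads the trace dialect used throughout the package: a CSV with columns
#' `time_s,do_mg_l,temp_c` and optionally `phase` (per-sample phase label), plus
#' an optional sidecar phase-mark CSV `start_s,end_s,phase`. When only a
#' per-sample `phase` column is present, phase intervals are reconstructed from
#' its runs (each run ends where the next begins; the final run is closed at the
#' last sample time plus one median sampling interval).
#'
#' @param path trace CSV path.
#' @param phase_path optional sidecar CSV of phase marks; takes precedence over
#'   a per-sample `phase` column.
#' @param chamber_id chamber identifier; defaults to the file name stem.
#' @return A validated [do_trace()] with the median sampling interval recorded
#'   in `meta$sample_interval_s`.
#' @export
read_do_trace <- function(path, phase_path = NULL, chamber_id = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "do_mg_l", "temp_c")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("trace file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in need) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !anyNA(v)) {
        stop("column ", col, " in ", path, " is not numeric")
      }
      raw[[col]] <- v2
    }
  }
  phases <- NULL
  if (!is.null(phase_path)) {
    if (!file.exists(phase_path)) stop("phase file not found: ", phase_path)
    phases <- utils::read.csv(phase_path, stringsAsFactors = FALSE)
  } else if ("phase" %in% names(raw) && nrow(raw) > 0L) {
    r <- rle(as.character(raw$phase))
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    dt <- if (nrow(raw) > 1L) stats::median(diff(raw$time_s)) else 1
    run_start_t <- raw$time_s[starts]
    phases <- data.frame(
      start_s = run_start_t,
      end_s = c(run_start_t[-1L], raw$time_s[nrow(raw)] + dt),
      phase = r$values, stringsAsFactors = FALSE)
    ## drop runs labelled "" or NA (unsegmented stretches)
    phases <- phases[!is.na(phases$phase) & nzchar(phases$phase), , drop = FALSE]
  }
  if (is.null(chamber_id)) {
    chamber_id <- sub("\\.[^.]*$", "", basename(path))
  }
  dt <- if (nrow(raw) > 1L) stats::median(diff(raw$time_s)) else NA_real_
  do_trace(raw[need], phases = phases, chamber_id = chamber_id,
           meta = list(sample_interval_s = dt, source = path))
}

#' Write a dissolved-oxygen trace to CSV
#'
#' Numbers are serialized at full double precision (17 significant digits), so
#' `read_do_trace(write_do_trace(tr))` reproduces the samples exactly. Phase
#' marks are written to a sidecar CSV.
#'
#' @param trace a [do_trace()].
#' @param path output CSV path.
#' @param phase_path sidecar path for phase marks; default replaces the file
#'   extension with `_phases.csv`. Only written when the trace has phase marks.
#' @return `path`, invisibly.
#' @export
write_do_trace <- function(trace, path,
                           phase_path = default_phase_path(path)) {
  validate_do_trace(trace)
  s <- trace$samples
  out <- data.frame(time_s = .fmt_num(s$time_s),
                    do_mg_l = .fmt_num(s$do_mg_l),
                    temp_c = .fmt_num(s$temp_c))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (nrow(trace$phases) > 0L) {
    p <- data.frame(start_s = .fmt_num(trace$phases$start_s),
                    end_s = .fmt_num(trace$phases$end_s),
                    phase = trace$phases$phase)
    utils::write.csv(p, phase_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

default_phase_path <- function(path) {
  sub("(\\.[^.]*)?$", "_phases.csv", path)
}

#' Respirometer and slope-extraction configuration
#'
#' Bundles the physical chamber description with the cycle timing and slope
#' windowing used for oxygen-uptake extraction. Defaults follow a common
#' salmonid protocol: a 6.1-litre chamber flushed for 2 min between 10-min
#' closed periods, the first 4 min of each closed period excluded, and one
#' 6-min regression window per closed period (at 2 degrees C a 22-min closed
#' period with two 6-min windows is typical; see [config_for_temp()]).
#'
#' @param volume_l chamber volume (litres).
#' @param flush_s flush (water-exchange) phase duration, seconds.
#' @param closed_s closed (sealed) phase duration, seconds.
#' @param exclusion_s initial portion of each closed phase excluded from slope
#'   fitting, seconds.
#' @param slope_window_s regression window length, seconds.
#' @param n_slopes_per_closed number of consecutive windows per closed phase.
#' @param fish_mass_kg fish body mass (kg); used for effective volume and
#'   mass-specific rates.
#' @param fish_density_kg_per_l assumed fish tissue density for water
#'   displacement; effective volume is `volume_l - fish_mass_kg / density`.
#' @return An object of class `respirometer_config`.
#' @export
respirometer_config <- function(volume_l = 6.1, flush_s = 120, closed_s = 600,
                                exclusion_s = 240, slope_window_s = 360,
                                n_slopes_per_closed = 1L,
                                fish_mass_kg = 0.146,
                                fish_density_kg_per_l = 1.0) {
  cfg <- list(volume_l = as.numeric(volume_l), flush_s = as.numeric(flush_s),
              closed_s = as.numeric(closed_s),
              exclusion_s = as.numeric(exclusion_s),
              slope_window_s = as.numeric(slope_window_s),
              n_slopes_per_closed = as.integer(n_slopes_per_closed),
              fish_mass_kg = as.numeric(fish_mass_kg),
              fish_density_kg_per_l = as.numeric(fish_density_kg_per_l))
  if (cfg$volume_l <= 0) stop("volume_l must be positive")
  if (cfg$flush_s < 0 || cfg$closed_s <= 0) {
    stop("phase durations must be positive")
  }
  if (cfg$exclusion_s < 0 || cfg$slope_window_s <= 0 ||
      cfg$n_slopes_per_closed < 1L) {
    stop("window settings must be positive")
  }
  if (cfg$exclusion_s + cfg$n_slopes_per_closed * cfg$slope_window_s >
      cfg$closed_s) {
    stop("exclusion_s + n_slopes_per_closed * slope_window_s exceeds closed_s")
  }
  if (cfg$fish_mass_kg < 0 || cfg$fish_density_kg_per_l <= 0) {
    stop("fish mass must be non-negative and density positive")
  }
  if (cfg$fish_mass_kg / cfg$fish_density_kg_per_l >= cfg$volume_l) {
    stop("fish volume (mass/density) must be smaller than chamber volume")
  }
  structure(cfg, class = "respirometer_config")
}

#' @export
print.respirometer_config <- function(x, ...) {
  cat("<respirometer_config>\n")
  cat(sprintf("  chamber %.2f l, fish %.3f kg (V_eff %.3f l)\n",
              x$volume_l, x$fish_mass_kg, effective_volume(x)))
  cat(sprintf("  cycle: flush %gs / closed %gs; exclude first %gs, %d x %gs window(s)\n",
              x$flush_s, x$closed_s, x$exclusion_s, x$n_slopes_per_closed,
              x$slope_window_s))
  invisible(x)
}

#' Effective (water) volume of the chamber
#'
#' The fish displaces water: `V_eff = volume_l - fish_mass_kg / density`.
#'
#' @param resp a [respirometer_config()].
#' @return Effective volume in litres.
#' @export
effective_volume <- function(resp) {
  v <- resp$volume_l - resp$fish_mass_kg / resp$fish_density_kg_per_l
  if (v <= 0) stop("effective chamber volume is non-positive")
  v
}

#' Read a respirometer configuration from YAML
#'
#' YAML keys match the arguments of [respirometer_config()]; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A validated [respirometer_config()].
#' @export
read_respirometer_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(respirometer_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(respirometer_config, vals)
}

#' Infer flush/closed phase marks from cycle timing
#'
#' For traces logged without phase annotations, reconstructs the alternating
#' phase structure from the configured cycle, assuming the trace starts at the
#' beginning of a phase.
#'
#' @param trace a [do_trace()].
#' @param resp a [respirometer_config()].
#' @param start_phase phase at `time_s = 0`, `"flush"` or `"closed"`.
#' @return The trace with phase marks filled in.
#' @export
infer_phases <- function(trace, resp, start_phase = c("flush", "closed")) {
  start_phase <- match.arg(start_phase)
  s <- trace$samples
  if (nrow(s) == 0L) return(trace)
  t_end <- max(s$time_s) + 1e-9
  durs <- if (start_phase == "flush") c(resp$flush_s, resp$closed_s) else
    c(resp$closed_s, resp$flush_s)
  labs <- if (start_phase == "flush") c("flush", "closed") else
    c("closed", "flush")
  starts <- numeric(0); ends <- numeric(0); phase <- character(0)
  t0 <- 0; i <- 1L
  while (t0 < t_end) {
    d <- durs[(i - 1L) %% 2L + 1L]
    starts <- c(starts, t0); ends <- c(ends, t0 + d)
    phase <- c(phase, labs[(i - 1L) %% 2L + 1L])
    t0 <- t0 + d; i <- i + 1L
  }
  trace$phases <- data.frame(start_s = starts, end_s = ends, phase = phase,
                             stringsAsFactors = FALSE)
  validate_do_trace(trace)
  trace
}

## phase label for each sample under half-open [start, end) intervals
sample_phase <- function(trace) {
  s <- trace$samples
  p <- trace$phases
  out <- rep(NA_character_, nrow(s))
  if (nrow(p) == 0L) return(out)
  for (i in seq_len(nrow(p))) {
    sel <- s$time_s >= p$start_s[i] & s$time_s < p$end_s[i]
    out[sel] <- p$phase[i]
  }
  out
}
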