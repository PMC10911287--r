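#' Estimate standard metabolic rate from repeated MO2 measurements
#'
#' The standard metabolic rate of an inactive, post-absorptive ectotherm is
#' taken as a low quantile — by default the 0.20 quantile, with linear
#' interpolation between order statistics (R quantile type 7) — of the
#' QC-passed mass-specific uptake measurements falling in the final
#' `window_h` hours of the record. Repeated measurements include spontaneous
#' activity bouts; the low quantile rejects those elevated values where a mean
#' would not. A `"mean_below_p"` alternative (mean of the measurements at or
#' below the p-quantile) is provided since several such estimators are in
#' common use and typically agree.
#'
#' @param records an `mo2_records` data.frame from [extract_mo2()], or a bare
#'   numeric vector of mass-specific MO2 values (then `window_h` is ignored).
#' @param window_h analysis window measured back from the last record, hours.
#' @param quantile_p quantile in (0, 1); default 0.20.
#' @param method `"quantile"` or `"mean_below_p"`.
#' @param min_records minimum number of usable records required.
#' @param ... unused.
#' @return SMR, mg O2 kg^-1 h^-1.
#' @examples
#' estimate_smr(1:100)          # 0.2 quantile by interpolation: 20.8
#' @export
estimate_smr <- function(records, window_h = 24, quantile_p = 0.20,
                         method = c("quantile", "mean_below_p"),
                         min_records = 20, ...) {
  UseMethod("estimate_smr")
}

#' @export
estimate_smr.default <- function(records, window_h = 24, quantile_p = 0.20,
                                 method = c("quantile", "mean_below_p"),
                                 min_records = 20, ...) {
  method <- match.arg(method)
  x <- as.numeric(records)
  x <- x[!is.na(x)]
  .smr_quantile(x, quantile_p, method, min_records)
}

#' @export
estimate_smr.mo2_records <- function(records, window_h = 24, quantile_p = 0.20,
                                     method = c("quantile", "mean_below_p"),
                                     min_records = 20, ...) {
  method <- match.arg(method)
  x <- .final_window_values(records, window_h)
  .smr_quantile(x, quantile_p, method, min_records)
}

.final_window_values <- function(records, window_h) {
  ok <- records[records$qc_pass & !is.na(records$mo2_mgkg_h), , drop = FALSE]
  if (nrow(ok) == 0L) return(numeric(0))
  cutoff <- max(ok$t_mid_s) - window_h * 3600
  ok$mo2_mgkg_h[ok$t_mid_s >= cutoff]
}

.smr_quantile <- function(x, p, method, min_records) {
  if (p <= 0 || p >= 1) stop("quantile_p must be in (0, 1)")
  if (length(x) < min_records) {
    stop("too few usable MO2 records for SMR: have ", length(x),
         ", need ", min_records)
  }
  q <- unname(stats::quantile(x, probs = p, type = 7))
  if (method == "quantile") q else mean(x[x <= q])
}

#' Average MO2 over the analysis window
#'
#' Arithmetic mean of the QC-passed mass-specific measurements in the final
#' `window_h` hours; unlike the SMR quantile this incorporates spontaneous
#' activity.
#'
#' @inheritParams estimate_smr
#' @return Mean MO2, mg O2 kg^-1 h^-1.
#' @export
estimate_average_mo2 <- function(records, window_h = 24, min_records = 20) {
  x <- if (inherits(records, "mo2_records")) {
    .final_window_values(records, window_h)
  } else {
    v <- as.numeric(records); v[!is.na(v)]
  }
  if (length(x) < min_records) {
    stop("too few usable MO2 records for average MO2: have ", length(x),
         ", need ", min_records)
  }
  mean(x)
}

#' Detect maximum metabolic rate by steepest sliding-window slope
#'
#' Slides a window of `window_s` seconds sample-by-sample through every closed
#' phase of a post-chase trace (windows never span a flush: the closed-system
#' assumption fails there), fits the OLS DO slope in each admissible position,
#' applies the background correction, converts to mass-specific uptake, and
#' returns the maximum. Ties are broken in favour of the earliest window.
#' Implemented with exact prefix-sum regression algebra on phase-centered
#' time, so a dense search over tens of thousands of start positions is cheap.
#'
#' @param trace post-chase [do_trace()] beginning at the end of the chase.
#' @param resp a [respirometer_config()].
#' @param window_s sliding-window length, seconds (90 by convention).
#' @param background optional background slope (mg O2 l^-1 h^-1, numeric) or
#'   empty-chamber [do_trace()].
#' @param min_samples minimum samples per window.
#' @return list with `mmr` (mg O2 kg^-1 h^-1), `slope` (mg O2 l^-1 h^-1),
#'   `window` (`c(start_s, end_s)`) and `n_windows` searched.
#' @export
detect_mmr <- function(trace, resp, window_s = 90, background = NULL,
                       min_samples = 3L) {
  stopifnot(inherits(trace, "do_trace"), inherits(resp, "respirometer_config"))
  p <- trace$phases
  closed <- p[p$phase == "closed", , drop = FALSE]
  if (nrow(closed) == 0L) stop("no closed phases in trace; cannot detect MMR")
  closed <- closed[order(closed$start_s), , drop = FALSE]
  s <- trace$samples
  bg <- NA_real_
  if (inherits(background, "do_trace")) {
    bg_resp <- resp
    bg_resp$fish_mass_kg <- 0
    tab <- background_slopes(background, bg_resp)
    bg <- if (nrow(tab) > 0L) mean(tab$slope) else NA_real_
  } else if (is.numeric(background) && length(background) == 1L) {
    bg <- background
  }
  best <- NULL
  n_windows <- 0L
  for (i in seq_len(nrow(closed))) {
    sel <- which(s$time_s >= closed$start_s[i] & s$time_s < closed$end_s[i])
    if (length(sel) < min_samples) next
    t <- s$time_s[sel] - closed$start_s[i]      # center within phase
    y <- s$do_mg_l[sel]
    res <- .steepest_window(t, y, window_s, min_samples)
    if (is.null(res)) next
    n_windows <- n_windows + res$n_windows
    if (is.null(best) ||
        res$slope < best$slope - (abs(best$slope) * 1e-9 + 1e-15)) {
      best <- res
      best$window <- res$window + closed$start_s[i]
    }
  }
  if (is.null(best)) {
    stop("no closed segment admits a ", window_s, "-s window with >= ",
         min_samples, " samples")
  }
  slope_h <- best$slope * 3600
  corrected <- if (!is.na(bg)) slope_h - bg else slope_h
  mo2 <- slope_to_mo2(corrected, resp)
  list(mmr = mo2$mo2_mgkg_h, slope = corrected, window = best$window,
       background_corrected = !is.na(bg), n_windows = n_windows)
}

## steepest (most negative) OLS slope of any [t_j, t_j + w) window via prefix
## sums; returns slope per second and the winning window, earliest on ties
.steepest_window <- function(t, y, w, min_samples) {
  n <- length(t)
  ends <- findInterval(t + w, t, left.open = TRUE)   # last index with t < t_j + w
  valid <- which(t + w <= t[n] + 1e-9 & (ends - seq_len(n) + 1L) >= min_samples)
  if (length(valid) == 0L) return(NULL)
  ct <- cumsum(t); ct2 <- cumsum(t * t)
  cy <- cumsum(y); cty <- cumsum(t * y)
  j <- valid
  k <- ends[valid]
  m <- k - j + 1
  st <- ct[k] - ct[j] + t[j]
  st2 <- ct2[k] - ct2[j] + t[j]^2
  sy <- cy[k] - cy[j] + y[j]
  sty <- cty[k] - cty[j] + t[j] * y[j]
  sxx <- st2 - st * st / m
  sxy <- sty - st * sy / m
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  ok <- which(!is.na(slope))
  if (length(ok) == 0L) return(NULL)
  ## earliest window wins among numerical ties (exactly repeated slopes on a
  ## plateau differ only by floating-point jitter)
  smin <- min(slope[ok])
  tol <- abs(smin) * 1e-9 + 1e-15
  best <- ok[which(slope[ok] <= smin + tol)[1L]]
  list(slope = slope[best], window = c(t[j[best]], t[j[best]] + w),
       n_windows = length(valid))
}

#' Absolute aerobic scope
#'
#' `AAS = MMR - SMR`, both in the same mass-specific units for the same fish
#' and day. A maximum below the standard rate is physiologically impossible
#' and produces a warning, but the (negative) value is returned so the caller
#' can flag it.
#'
#' @param smr standard metabolic rate.
#' @param mmr maximum metabolic rate.
#' @return `mmr - smr`.
#' @export
aerobic_scope <- function(smr, mmr) {
  out <- mmr - smr
  if (any(!is.na(out) & out < 0)) {
    warning("MMR below SMR: negative aerobic scope returned")
  }
  out
}

#' Q10 thermal sensitivity
#'
#' The factor by which a rate changes per 10 degrees C:
#' `Q10 = (R2 / R1)^(10 / (T2 - T1))` with `R2` the rate at the higher
#' temperature `T2`. Inputs may be supplied in either order; the pair is
#' normalized so that `t2 > t1`.
#'
#' @param r1,r2 rates (> 0) at temperatures `t1`, `t2`.
#' @param t1,t2 temperatures, degrees C (`t1 != t2`).
#' @return Dimensionless Q10.
#' @examples
#' q10(0.23, 1.00, 2, 14)   # 77% decline over 14 -> 2 C: ~3.4
#' @export
q10 <- function(r1, r2, t1, t2) {
  if (any(c(r1, r2) <= 0)) stop("rates must be positive")
  if (any(t1 == t2)) stop("t1 and t2 must differ")
  swap <- t1 > t2
  if (any(swap)) {
    tmp_r <- r1; tmp_t <- t1
    r1 <- ifelse(swap, r2, r1); t1 <- ifelse(swap, t2, t1)
    r2 <- ifelse(swap, tmp_r, r2); t2 <- ifelse(swap, tmp_t, t2)
  }
  (r2 / r1)^(10 / (t2 - t1))
}

#' Per-fish metabolic summary
#'
#' Assembles SMR, average MO2, MMR and aerobic scope (when a maximum was
#' measured) with the estimator settings used, checking internal consistency.
#'
#' @param fish_id identifier.
#' @param day measurement day.
#' @param smr,mo2_average,mmr mass-specific rates (mg O2 kg^-1 h^-1); `mmr`
#'   may be `NA` when no chase trial was run.
#' @param quantile_p,window_h,mmr_window_s estimator settings recorded as
#'   method metadata.
#' @param n_measurements number of QC-passed measurements behind the
#'   estimates.
#' @return An object of class `metabolic_summary`.
#' @export
metabolic_summary <- function(fish_id, day, smr, mo2_average, mmr = NA_real_,
                              quantile_p = 0.20, window_h = 24,
                              mmr_window_s = 90, n_measurements = NA_integer_) {
  if (!is.na(smr) && !is.na(mo2_average) && smr > mo2_average + 1e-9) {
    warning("SMR exceeds average MO2; check the record set")
  }
  aas <- if (is.na(mmr)) NA_real_ else aerobic_scope(smr, mmr)
  structure(list(fish_id = as.character(fish_id), day = day, smr = smr,
                 mo2_average = mo2_average, mmr = mmr, aas = aas,
                 method = list(quantile_p = quantile_p, window_h = window_h,
                               mmr_window_s = mmr_window_s),
                 n_measurements = n_measurements),
            class = "metabolic_summary")
}

#' @export
print.metabolic_summary <- function(x, ...) {
  cat(sprintf("<metabolic_summary> fish %s, day %g\n", x$fish_id, x$day))
  cat(sprintf("  SMR %.2f | average %.2f", x$smr, x$mo2_average))
  if (!is.na(x$mmr)) cat(sprintf(" | MMR %.2f | AAS %.2f", x$mmr, x$aas))
  cat(" mg O2/kg/h\n")
  cat(sprintf("  method: p = %.2f over final %g h (%s measurements)\n",
              x$method$quantile_p, x$method$window_h,
              ifelse(is.na(x$n_measurements), "?", x$n_measurements)))
  invisible(x)
}
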