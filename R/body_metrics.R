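#' Fulton's condition factor
#'
#' `K = 1e5 * mass_g / standard_length_mm^3`. The constant 10^5 is the
#' standard convention for gram/millimetre inputs (equivalently 100 with
#' centimetres) and puts salmonids near K = 1-1.5.
#'
#' @param mass_g body mass, g.
#' @param standard_length_mm standard length, mm.
#' @return Condition factor (dimensionless by convention).
#' @examples
#' fulton_k(137.78, 214.3)   # ~1.40
#' @export
fulton_k <- function(mass_g, standard_length_mm) {
  if (any(mass_g <= 0) || any(standard_length_mm <= 0)) {
    stop("mass and length must be positive")
  }
  1e5 * mass_g / standard_length_mm^3
}

#' Lean body mass
#'
#' `M_lean = mass * (1 - fat_frac)` with the body-fat fraction measured e.g.
#' by a fat meter. Output units follow the input mass.
#'
#' @param mass body mass (any unit).
#' @param fat_frac body fat as a proportion in `[0, 1)`.
#' @return Lean mass, same units as `mass`.
#' @export
lean_mass <- function(mass, fat_frac) {
  if (any(fat_frac < 0 | fat_frac >= 1)) stop("fat_frac must be in [0, 1)")
  if (any(mass <= 0)) stop("mass must be positive")
  mass * (1 - fat_frac)
}

#' Specific growth rate
#'
#' The standard fisheries log-difference form,
#' `SGR = 100 * (ln(mass_end) - ln(mass_start)) / days`, in percent per day;
#' negative under mass loss (starvation).
#'
#' @param mass_start,mass_end body mass at the start and end of the interval
#'   (same units).
#' @param days interval length, days (> 0).
#' @return SGR, % day^-1.
#' @export
specific_growth_rate <- function(mass_start, mass_end, days) {
  if (any(mass_start <= 0) || any(mass_end <= 0)) {
    stop("masses must be positive")
  }
  if (any(days <= 0)) stop("days must be positive")
  100 * (log(mass_end) - log(mass_start)) / days
}

#' Gut-to-heart mass ratio
#'
#' Total gut mass divided by ventricular mass. Being a ratio of two organ
#' masses it is invariant to uniform body-size scaling and less sensitive to
#' body-composition shifts (fat, water) than body-mass-based somatic indices.
#'
#' @param total_gut_mass total gut mass.
#' @param ventricle_mass ventricle mass, same units (> 0).
#' @return Dimensionless ratio.
#' @export
gut_heart_ratio <- function(total_gut_mass, ventricle_mass) {
  if (any(ventricle_mass <= 0)) stop("ventricle mass must be positive")
  if (any(total_gut_mass < 0)) stop("gut mass must be non-negative")
  total_gut_mass / ventricle_mass
}

#' Total organ content relative to lean body mass
#'
#' Total triglyceride or protein in an organ (concentration times organ mass)
#' expressed as a fraction of lean body mass. Concentration must be declared
#' in mass-per-mass units consistent with the two masses; when unit labels are
#' supplied they are checked and a mismatch is an error (no silent
#' conversion).
#'
#' @param concentration analyte concentration, mass per unit organ mass.
#' @param organ_mass organ mass.
#' @param lean_body_mass lean body mass, same units as `organ_mass`.
#' @param organ_unit,body_unit optional unit labels (e.g. `"g"`); checked for
#'   equality when both are given.
#' @return Fraction of lean body mass (dimensionless).
#' @export
total_relative_content <- function(concentration, organ_mass, lean_body_mass,
                                   organ_unit = NULL, body_unit = NULL) {
  if (!is.null(organ_unit) && !is.null(body_unit) &&
      !identical(organ_unit, body_unit)) {
    stop("unit mismatch: organ mass in ", organ_unit, " but body mass in ",
         body_unit)
  }
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (any(organ_mass < 0)) stop("organ mass must be non-negative")
  if (any(lean_body_mass <= 0)) stop("lean body mass must be positive")
  (concentration * organ_mass) / lean_body_mass
}

#' Fractional protein synthesis rate (flooding dose)
#'
#' The standard flooding-dose ratio form: the fraction of the tissue protein
#' pool synthesized per day is the ratio of label enrichment in protein-bound
#' phenylalanine to that of the (saturated) free pool, scaled from the
#' incorporation time to a day and expressed in percent:
#' `Ks = (bound / free) * (24 / time_h) * 100` (% day^-1).
#'
#' @param bound_enrichment labelled fraction in protein-bound phenylalanine,
#'   in `[0, 1]`.
#' @param free_enrichment labelled fraction in the free pool, in `(0, 1]`.
#' @param incorporation_time_h time from tracer injection to sampling, hours.
#' @return Ks, % day^-1.
#' @examples
#' fractional_synthesis_rate(0.01, 0.5, 4)   # 12 % per day
#' @export
fractional_synthesis_rate <- function(bound_enrichment, free_enrichment,
                                      incorporation_time_h) {
  if (any(free_enrichment <= 0)) stop("free-pool enrichment must be positive")
  if (any(bound_enrichment < 0 | bound_enrichment > 1) ||
      any(free_enrichment > 1)) {
    stop("enrichments must be fractions in [0, 1]")
  }
  if (any(incorporation_time_h <= 0)) {
    stop("incorporation time must be positive")
  }
  (bound_enrichment / free_enrichment) * (24 / incorporation_time_h) * 100
}

#' Squeeze proportions off the boundaries
#'
#' Beta-family models reject exact 0 or 1; the conventional transform
#' `y' = (y * (n - 1) + 0.5) / n` maps observed proportions strictly inside
#' `(0, 1)`, with `n` the sample size. `y = 0.5` is a fixed point.
#'
#' @param y observed proportion(s) in `[0, 1]`.
#' @param n sample size (>= 1).
#' @return Transformed proportion(s) in `(0, 1)`.
#' @export
proportion_transform <- function(y, n) {
  if (any(y < 0 | y > 1)) stop("proportions must lie in [0, 1]")
  if (any(n < 1)) stop("sample size must be >= 1")
  (y * (n - 1) + 0.5) / n
}

#' Average swimming speed in body lengths per minute
#'
#' Total path length (sum of consecutive Euclidean steps, converted from
#' pixels through the calibration) divided by the recording duration and by
#' the fish's body length.
#'
#' @param t_s sample times, seconds (>= 2 samples spanning > 0 s).
#' @param x,y positions, pixels (or mm with `px_per_mm = 1`).
#' @param body_length_mm fish body length, mm.
#' @param px_per_mm pixel-to-mm calibration.
#' @return Average speed, body lengths per minute.
#' @export
average_speed <- function(t_s, x, y, body_length_mm, px_per_mm = 1) {
  n <- length(t_s)
  if (n < 2L || length(x) != n || length(y) != n) {
    stop("need >= 2 aligned position samples")
  }
  if (body_length_mm <= 0 || px_per_mm <= 0) {
    stop("body length and calibration must be positive")
  }
  dur_min <- (max(t_s) - min(t_s)) / 60
  if (dur_min <= 0) stop("recording duration must be positive")
  dist_mm <- sum(sqrt(diff(x)^2 + diff(y)^2)) / px_per_mm
  (dist_mm / dur_min) / body_length_mm
}
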