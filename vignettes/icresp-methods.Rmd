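---
title: "Methods: respirometry processing, metabolic estimators, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry processing, metabolic estimators, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icresp)
```

`icresp` processes intermittent-closed (intermittent-flow) respirometry of
fishes into whole-animal energetic metrics, and ships a physics-based
simulator of the chamber and the fish so that every estimator in the chain
can be validated against known ground truth. This vignette is the package's
account of the underlying models, the tunable parameters, the numerical
choices, and what the simulator does and does not capture.

## The measurement model

In intermittent-closed respirometry a chamber of volume $V$ alternates
between *flush* phases (water exchange with the aerated reservoir) and
*closed* phases (sealed). While sealed, the fish's oxygen uptake draws down
the dissolved oxygen (DO), and the uptake rate follows from the DO slope:

$$\dot{M}_{O_2} = -\,b \cdot V_\mathrm{eff}, \qquad
  V_\mathrm{eff} = V - m/\rho,$$

where $b$ is the fitted DO slope (mg O$_2$ l$^{-1}$ h$^{-1}$, negative while
the fish consumes), $m$ is body mass and $\rho \approx 1$ kg l$^{-1}$ the
assumed tissue density — the fish displaces its own volume of water.
Mass-specific uptake divides by $m$. Microbial (background) consumption,
measured in a simultaneously logged empty chamber, is subtracted from the
fish-chamber slope before conversion.

Each closed phase is reduced to one or more regression windows
(`segment_cycles()`): the first 4 min are excluded (mixing and flush
carry-over violate the closed, well-mixed assumption early in the seal), and
consecutive non-overlapping windows of 6 min are laid down from the exclusion
boundary — one window in a 10-min closed phase, two in a 22-min one. The
two-window placement immediately after the exclusion (minutes 4–10 and
10–16 of the seal) is a design choice; the tail of the long seal is left
unused. Placing both windows early keeps them closest in time to the flush
reset, where DO is highest and the linear approximation best.

Windows are fitted by ordinary least squares on time-centered samples. QC
never drops records silently: windows with fewer than 3 samples, zero DO
variance, a positive corrected slope, or $r^2$ below a configurable
threshold are flagged with a reason and retained; estimators exclude flagged
records by default and report counts.

### On the $r^2$ threshold

`extract_mo2()` defaults to `r2_min = 0.9`, a common screening rule.
`run_pipeline()`, however, defaults to `r2_min = 0` (no $r^2$ gate). The
reason is statistical, not cosmetic: $r^2$ of a window is a signal-to-noise
ratio, and the *signal* (the true DO decline) shrinks with temperature and
starvation while the optode noise does not. At 2 °C a starved fish draws DO
down by only ~0.04–0.13 mg l$^{-1}$ per 6-min window; with 0.01 mg l$^{-1}$
sensor noise an unbiased, perfectly valid window then has $r^2 \approx 0.5$.
An absolute $r^2$ gate therefore censors precisely the low-rate measurements
the SMR estimator needs — and preferentially *retains* activity-elevated
windows, biasing SMR upward in the coldest, most depressed groups. The low
quantile used for SMR is already robust to occasional bad windows; raise the
gate only when noise is small relative to the slope signal.

## Estimators

**Standard metabolic rate (SMR).** Fish in chambers are mostly quiescent but
show spontaneous activity bouts, so repeated $\dot{M}_{O_2}$ measurements
are a mixture of resting and elevated values. SMR is estimated as the 0.20
quantile (linear interpolation between order statistics, R's type-7
convention, stated here as the package's fixed convention) of the QC-passed
mass-specific measurements in the final 24 h of a trial. A
`"mean_below_p"` alternative (mean of the values at or below that quantile)
is provided; such variants are in common use and ordinarily agree.

**Average $\dot{M}_{O_2}$** is the plain mean over the same window and, by
construction, absorbs the activity bouts the quantile rejects; on simulated
data with activity on, the mean exceeds the quantile by roughly the activity
duty cycle times the excess multiplier.

**Maximum metabolic rate (MMR).** After an exhaustive chase the steepest
90-s DO slope is found by a dense sliding-window search: every sample index
in every closed phase starts a candidate window; windows never span a flush.
The search uses exact prefix-sum regression algebra on phase-centered time
(centering keeps the normal-equation cancellation benign), and ties are
broken in favour of the earliest window, with a $10^{-9}$ relative tolerance
so that exact plateaus — where adjacent windows differ only by
floating-point jitter — resolve deterministically. The unit tests hold this
search to exact agreement with a brute-force per-window re-fit.

**Aerobic scope** is $\mathrm{AAS} = \mathrm{MMR} - \mathrm{SMR}$; a
negative value (possible only through estimation error) is returned with a
warning rather than masked.

**Thermal sensitivity.** $Q_{10} = (R_2/R_1)^{10/(T_2-T_1)}$ with $R_2$ at
the warmer temperature; arguments may be given in either order and are
normalized. The identity $R_1 \cdot Q_{10}^{(T_2-T_1)/10} = R_2$ holds to
machine precision.

**Residual size adjustment.** Oxygen uptake and organ masses scale
allometrically, so group comparisons are made at a common body size: a
linear model `response ~ covariate (+ group)` is fitted and each
individual's residual is added to its group's prediction at the reference
size (`mass_adjust()`, the package's model object with the usual
`coef`/`predict`/`residuals`/`plot` methods). Residuals are always applied
on the response scale, also under the optional log link. Somatic indices
(`somatic_index()`) divide the adjusted organ mass by the reference size and
express it in percent; reference values of 0.146 kg body mass, 0.154 kg lean
mass (final day, when body fat is measured) and 0.152 kg / 225 mm for organ
indices follow common practice for fish of this size class. A constant
covariate makes the model singular; the fit falls back to group means with a
warning, which leaves each observation unchanged.

## The simulator

The simulator has two layers.

**The fish.** `true_resting_rate()` composes three factors on top of a
reference rate `smr_ref` (65 mg O$_2$ kg$^{-1}$ h$^{-1}$ at 8 °C — a typical
resting rate for a ~0.15-kg cold-water salmonid):

1. *Acute thermal scaling*: $Q_{10,\mathrm{acute}}^{(T - T_\mathrm{ref})/10}$
   with default $Q_{10} = 4.3$, the strong acute response of a cold-water
   fish cooled quickly below its acclimation temperature.
2. *Thermal compensation*: the acute factor relaxes exponentially (e-folding
   time `tau_acclim_days = 25`) towards a compensated level in which
   `compensation_frac = 0.63` of the acute change has been recovered. Over
   an 8 → 2 °C step this yields an acclimated $Q_{10} \approx 1.5$, with
   $\approx 1.9$ at 30 days and $\approx 1.6$ at 60 days. The exponential
   form is the simplest dynamics consistent with a monotone multi-week
   trajectory; it is a modelling choice, not a mechanistic claim.
3. *Starvation depression*: a multiplicative
   $1 - d\,(1 - e^{-t/\tau_s})$ with asymptote `starve_depression_frac
   = 0.44` and `tau_starve_days = 12`, giving roughly a quarter of the full
   depression within 10 days and ~44% by 90 days.

Spontaneous activity is a two-state (rest/active) discrete-time Markov chain
at 1-min resolution (`p_active_per_min = 0.05`, `p_rest_per_min = 0.40`,
~11% duty), multiplying uptake by `activity_multiplier = 2.5` while active —
enough intermittent elevation to separate the quantile SMR estimator from
the mean. Post-chase, uptake starts at `mmr_ref = 250` mg O$_2$ kg$^{-1}$
h$^{-1}$ and decays towards resting with `recovery_tau_min = 60`.

Within a single trace the metabolic state is *frozen at the measurement
day*: acclimation and starvation clocks advance between measurement days,
not within a 24-h trial. This snapshot approximation (the clocks move by at
most one day per trial) is what makes the noiseless pipeline invert the
generator exactly, which the tests exploit.

**The chamber.** During closed phases DO declines at
$(u \cdot m + B)/V_\mathrm{eff}$ with $u$ the instantaneous mass-specific
uptake and $B$ a constant background rate; the integration is exact for
piecewise-constant $u$, so noiseless closed-phase DO is exactly piecewise
linear. During flushes DO relaxes exponentially towards the Benson–Krause
saturation concentration at the water temperature (rate constant
$3/\mathrm{flush}_s$, i.e. ~95% recovery per flush). Measurement noise is
i.i.d. Gaussian on the observed DO (`noise_sd`, default 0.01 mg l$^{-1}$, a
realistic optode figure); there is no drift term — slow drift can be
emulated through the background rate. Observed DO is clamped at zero. The
post-chase protocol is emulated as recorded in practice: a long first seal
(~2 mg l$^{-1}$ drawdown), then short flush/seal cycles of ~0.5 mg l$^{-1}$
each, so the steepest window always lies at the start of the first seal.
All stochastic operations take explicit seeds and restore the caller's RNG
state; identical seeds give identical traces.

**The cohort.** `simulate_cohort()` draws per-fish initial masses
(lognormal around 137.78 g) and derives lengths from a condition factor of
~1.40. Fed fish grow at ~0.2% day$^{-1}$, starved fish lose ~0.12%
day$^{-1}$; body fat runs linearly from 9% to 10% (fed) or 3% (starved)
while moisture rises in starved fish. At dissection, organ masses scale as
$\mathrm{mass}^{0.9}$ with lognormal individual scatter, and starved fish
carry multiplicative offsets: digestive organs ×0.6 (40% atrophy), liver
×0.65, ventricle spared — the classic starvation pattern of non-essential
tissue catabolism with cardiac protection. Tissue triglyceride falls
strongly with starvation while protein concentration is spared, and
fractional protein-synthesis rates (`ks`) are roughly halved in the gut and
liver. All generating values are returned as ground truth so recovery can
be asserted, and setting the noise parameters to zero with equal group
effects produces exactly identical groups (the null case).

### What the simulator does *not* emulate

Real optode data carry autocorrelated drift, temperature transients during
flushes, occasional dropouts, and fish whose activity is diurnally
structured rather than Markovian; chambers differ in mixing efficiency; and
real cohorts have individual metabolic phenotypes (consistent among-fish
rate differences) beyond the mass effect. Passing tests against this
simulator therefore demonstrates the correctness of the *estimators* under
the stated physics, not robustness to every field artefact. The
body-composition trajectories are descriptive (linear/exponential forms with
plausible endpoints), not bioenergetically closed — energy is not conserved
across fat, growth and metabolic rate.

## The end-to-end pipeline

`run_pipeline()` carries a full 2 × 2 (temperature × feeding) design through
trace simulation (or ingestion of previously written CSVs), extraction,
estimation, Q10 tables (between temperatures within each feeding treatment
at every measurement day; the day-0 row is the acute response), residual
mass adjustment, and starved-vs-fed contrasts at the final day, with a
deterministic seed and a JSON manifest. Missing or failed fish-day estimates
are recorded and the run continues. `report()` prints group trajectories,
the Q10 table, contrasts and QC counts; every number it shows is a cell of
the bundle's tables.

Default problem sizes — 8 fish per group, four measurement days, 24-h traces
at a 5-s sampling interval, 1-s post-chase traces — were chosen so that a
complete simulated experiment (128 daily traces plus 32 chase traces, about
2.2 million DO samples) runs in well under a minute on a single core while
leaving the estimators' sampling error small relative to the effects being
recovered. With those defaults and the parameter defaults above, a seeded
run recovers an acute $Q_{10}$ within a few percent of 4.3 (slightly
inflated by the noise-quantile interaction at the lowest rates), acclimated
$Q_{10}$ values of ~1.6 at 60 days and ~1.5 at 90 days, and a ~40–46%
starved-vs-fed SMR reduction at day 90 — the quantities
`scripts/acceptance.R` recomputes and prints.

## Degenerate inputs and numerical conventions

* Phase intervals are half-open `[start, end)`; a sample on a boundary
  belongs to the later interval. Trace time is seconds from trace start.
* Closed phases shorter than exclusion + window yield zero windows and a
  warning; a trace with no closed phases is an empty result, not an error.
* The SMR quantile is type 7 (R's default); the oracle tests pin the
  interpolation (`1:100` at $p = 0.2$ gives 20.8 exactly).
* Slope fits use centered time; the sliding MMR search additionally centers
  each phase at its own origin before forming prefix sums.
* Too few usable records is an error naming the count; positive corrected
  slopes produce negative uptake values that are flagged, never clipped.
* Background matching is nearest-in-time between window midpoints; the
  empty chamber holds slightly more water than the occupied one
  ($V$ vs $V_\mathrm{eff}$), leaving a sub-percent residual that is physical,
  not numerical.
* `fulton_k()` uses $10^5 \cdot m / SL^3$ for g/mm inputs; specific growth
  rate is the log-difference form; the flooding-dose synthesis rate uses the
  standard enrichment-ratio form
  $K_s = (S_b/S_f)\,(24/t)\cdot 100$ % day$^{-1}$ — all stated conventions
  of the field, fixed here as the package's definitions.

## Worked example

```{r example, eval = FALSE}
library(icresp)

cfg <- experiment_config(design = cohort_design(n_per_group = 8))
run <- run_pipeline(cfg, seed = 1)
report(run)
```

See the README for the printed output of this exact run and the
interpretation of each block.
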