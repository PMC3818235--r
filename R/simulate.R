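# Synthetic abdominal EMG with the statistical structure of UBD experiments:
# evoked activity is amplitude-modulated zero-mean Gaussian noise whose
# envelope grades with distension pressure and is multiplied by anesthesia
# and temperature factors. The rectified-integrated score depends on the
# signal only through this envelope, so no motor-unit detail is modeled.

#' Simulation parameters for synthetic EMG cohorts
#'
#' Defaults encode the qualitative phenomena of the UBD model at cohort size
#' n = 6: evoked amplitude grading with pressure above a threshold, a
#' progressive decline under the short isoflurane induction, stability under
#' the long induction, graded suppression by cooling below 37.5 C, and a
#' persistent (hysteretic) suppression once body temperature has reached
#' 33.5 C. Effect magnitudes are calibrated operating points for the
#' simulation studies, not physiological estimates.
#'
#' @param sampling_rate Hz (default 1000).
#' @param baseline_sd resting EMG noise scale, mV (default 0.05).
#' @param response_gain evoked envelope per unit drive, mV (default 0.02).
#' @param pressure_threshold mmHg below which evoked drive is 0 (default 10).
#' @param pressure_slope drive units per mmHg above threshold (default 1).
#' @param anesthesia_drift_rate per-hour exponential decline of the evoked
#'   response under the *short* induction only (default 0.7; 0 disables).
#' @param temp_sensitivity fractional suppression per degree C below 37.5
#'   (default 0.12; 0 disables).
#' @param hysteresis_floor once the session's minimum temperature has reached
#'   33.5 C, the temperature factor is capped at this value for the rest of
#'   the session (default 0.55; 1 disables).
#' @param animal_sd between-animal lognormal scale (sdlog) of the evoked
#'   gain (default 0.2; 0 disables).
#' @param n_animals cohort size (default 6).
#' @param seed master RNG seed; per-animal streams are derived
#'   deterministically from `(seed, animal index)`.
#' @param max_samples guard on trace length (default 5e7 samples).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 1000, baseline_sd = 0.05,
                       response_gain = 0.02, pressure_threshold = 10,
                       pressure_slope = 1, anesthesia_drift_rate = 0.7,
                       temp_sensitivity = 0.12, hysteresis_floor = 0.55,
                       animal_sd = 0.2, n_animals = 6, seed = 1,
                       max_samples = 5e7) {
  p <- list(sampling_rate = sampling_rate, baseline_sd = baseline_sd,
            response_gain = response_gain,
            pressure_threshold = pressure_threshold,
            pressure_slope = pressure_slope,
            anesthesia_drift_rate = anesthesia_drift_rate,
            temp_sensitivity = temp_sensitivity,
            hysteresis_floor = hysteresis_floor,
            animal_sd = animal_sd, n_animals = as.integer(n_animals),
            seed = as.integer(seed), max_samples = max_samples)
  stopifnot(p$sampling_rate > 0, p$baseline_sd > 0, p$response_gain >= 0,
            p$pressure_threshold >= 0, p$pressure_slope >= 0,
            p$anesthesia_drift_rate >= 0, p$animal_sd >= 0,
            p$temp_sensitivity >= 0, p$temp_sensitivity * 4 < 1,
            p$hysteresis_floor > 0, p$hysteresis_floor <= 1,
            p$n_animals >= 2)
  structure(p, class = "sim_params")
}

#' Null (effects-off) variant of simulation parameters
#'
#' Convenience for calibration studies: anesthesia drift, temperature
#' suppression, hysteresis and between-animal variability are all disabled,
#' leaving pure measurement noise around a pressure-graded envelope.
#' @param ... passed to [sim_params()].
#' @return `sim_params` with all systematic effects off.
#' @export
sim_params_null <- function(...) {
  sim_params(anesthesia_drift_rate = 0, temp_sensitivity = 0,
             hysteresis_floor = 1, animal_sd = 0, ...)
}

#' Pressure--response drive
#'
#' Deterministic stimulus drive: 0 at or below `pressure_threshold`, rising
#' linearly with slope `pressure_slope` above it, so evoked amplitude grades
#' with distension pressure over the 15--75 mmHg testing range.
#'
#' @param pressure mmHg (vectorized, must be >= 0).
#' @param params [sim_params()].
#' @return non-negative drive (unitless).
#' @export
pressure_response <- function(pressure, params) {
  if (any(pressure < 0)) stop("pressure must be non-negative")
  pmax(0, pressure - params$pressure_threshold) * params$pressure_slope
}

#' Anesthesia factor
#'
#' Multiplicative modulation of the evoked response by induction method and
#' elapsed testing time: the long step-down induction yields a stable
#' response (factor 1); the short induction decays exponentially at
#' `anesthesia_drift_rate` per hour.
#'
#' @param method `"short"` or `"long"`.
#' @param t seconds since start of testing (vectorized, >= 0).
#' @param params [sim_params()].
#' @return factor in (0, 1]; 1 at t = 0.
#' @export
anesthesia_factor <- function(method, t, params) {
  if (!is.character(method) || length(method) != 1 ||
      !method %in% c("short", "long"))
    stop("unknown anesthesia method: ", paste(method, collapse = ", "))
  if (any(t < 0)) stop("t must be non-negative")
  if (method == "long") rep(1, length(t))
  else exp(-params$anesthesia_drift_rate * t / 3600)
}

#' Temperature factor with cooling hysteresis
#'
#' Multiplicative suppression of the evoked response by hypothermia:
#' `1 - temp_sensitivity * (37.5 - current_temp)`, equal to 1 at 37.5 C and
#' strictly decreasing with cooling. Once the running minimum temperature of
#' the session has reached 33.5 C the factor is additionally capped at
#' `hysteresis_floor` regardless of the current temperature, so responses do
#' not recover after rewarming within a session.
#'
#' @param current_temp degrees C in \[33.5, 37.5\] (vectorized).
#' @param min_temp_reached running minimum temperature of the session so far
#'   (scalar or vector, same range, `<= current_temp` elementwise).
#' @param params [sim_params()].
#' @return factor in (0, 1].
#' @export
temperature_factor <- function(current_temp, min_temp_reached, params) {
  if (any(current_temp < 33.5 | current_temp > 37.5) ||
      any(min_temp_reached < 33.5 | min_temp_reached > 37.5))
    stop("temperatures must lie within the modeled range [33.5, 37.5] C")
  if (any(min_temp_reached > current_temp + 1e-9))
    stop("min_temp_reached cannot exceed current_temp")
  f <- 1 - params$temp_sensitivity * (37.5 - current_temp)
  ifelse(min_temp_reached <= 33.5, pmin(f, params$hysteresis_floor), f)
}

# Per-event evoked envelope amplitude (mV) for one animal.
event_envelope <- function(events, method, params, animal_gain) {
  drive <- pressure_response(events$pressure_mmHg, params)
  af <- anesthesia_factor(method, events$onset_s, params)
  tf <- temperature_factor(events$temp_C, cummin(events$temp_C), params)
  params$baseline_sd + animal_gain * params$response_gain * drive * af * tf
}

#' Simulate one animal's EMG trace for a protocol
#'
#' The trace is zero-mean Gaussian noise whose standard deviation equals
#' `baseline_sd` outside stimulus windows and, during each distension,
#' `baseline_sd + animal_gain * response_gain * drive * anesthesia_factor *
#' temperature_factor`. The animal gain is drawn once per animal from a
#' lognormal with sdlog `animal_sd`; the RNG stream is derived
#' deterministically from `(params$seed, animal_id)`, so repeated calls are
#' bit-identical.
#'
#' @param protocol a [build_protocol()] result.
#' @param params [sim_params()].
#' @param animal_id positive integer animal index.
#' @return list with `trace` ([emg_trace()]), `events` (the protocol events
#'   with an `animal` column), `animal_gain`, and `seed` actually used.
#' @export
simulate_trace <- function(protocol, params, animal_id = 1L) {
  validate_protocol(protocol)
  fs <- params$sampling_rate
  span <- protocol_span_s(protocol)
  n <- round(span * fs) + 1L
  if (n > params$max_samples)
    stop("trace of ", n, " samples exceeds max_samples cap (",
         params$max_samples, "); lower sampling_rate or raise the cap")
  seed <- derive_seed(params$seed, animal_id)
  set.seed(seed)
  gain <- exp(rnorm(1, 0, params$animal_sd))
  env <- rep(params$baseline_sd, n)
  ev <- protocol$events
  amp <- event_envelope(ev, protocol$anesthesia$method, params, gain)
  for (i in seq_len(nrow(ev))) {
    # stimulus owns the half-open window [onset, onset + duration)
    i0 <- round(ev$onset_s[i] * fs) + 1L
    i1 <- round((ev$onset_s[i] + ev$duration_s[i]) * fs)
    env[i0:i1] <- amp[i]
  }
  v <- rnorm(n) * env
  ev$animal <- animal_id
  list(trace = emg_trace(v, fs, start_time = 0),
       events = ev, animal_gain = gain, seed = seed)
}

#' Simulate a cohort of animals
#'
#' @param design a design name (see [build_protocol()]) or a `ubd_protocol`.
#' @param params [sim_params()]; `params$n_animals` traces are generated with
#'   per-animal seeds derived from `params$seed`.
#' @param overrides protocol overrides, used when `design` is a name.
#' @return list of per-animal results from [simulate_trace()].
#' @export
simulate_cohort <- function(design, params, overrides = list()) {
  if (params$n_animals < 2)
    stop("a cohort needs at least 2 animals for replicated analysis")
  protocol <- if (inherits(design, "ubd_protocol")) design
              else build_protocol(design, overrides)
  lapply(seq_len(params$n_animals),
         function(i) simulate_trace(protocol, params, animal_id = i))
}

#' Blot simulation parameters
#'
#' Lane-intensity generator for the 2 x 2 pERK design (temperature 37.5 or
#' 33.5 C crossed with distended/control, n per group). Defaults place the
#' distension effect on pERK2 at 37.5 C only, with the 33.5 C effect blunted
#' to baseline, matching the phenomenon that cooling prevents the
#' distension-evoked rise in spinal pERK2. pERK1 carries no effect.
#'
#' @param control_ratio_mean baseline pERK2/ERK2 ratio (default 1).
#' @param distension_effect_37 multiplicative pERK2 increase with distension
#'   at 37.5 C (default 1.8).
#' @param distension_effect_33 same at 33.5 C (default 1, i.e. blunted).
#' @param lane_cv lane-to-lane coefficient of variation (default 0.25).
#' @param n_per_group lanes per group (default 9).
#' @param erk_mean mean total-ERK band intensity, arbitrary densitometry
#'   units (default 100).
#' @param seed RNG seed.
#' @return object of class `blot_sim_params`.
#' @export
blot_sim_params <- function(control_ratio_mean = 1, distension_effect_37 = 1.8,
                            distension_effect_33 = 1, lane_cv = 0.25,
                            n_per_group = 9, erk_mean = 100, seed = 1) {
  p <- list(control_ratio_mean = control_ratio_mean,
            distension_effect_37 = distension_effect_37,
            distension_effect_33 = distension_effect_33,
            lane_cv = lane_cv, n_per_group = as.integer(n_per_group),
            erk_mean = erk_mean, seed = as.integer(seed))
  stopifnot(p$control_ratio_mean > 0, p$distension_effect_37 >= 1,
            p$distension_effect_33 > 0, p$lane_cv > 0, p$n_per_group >= 2,
            p$erk_mean > 0)
  structure(p, class = "blot_sim_params")
}

#' Simulate Western-blot lane intensities
#'
#' Generates `4 * n_per_group` lanes (temperature 37.5/33.5 C x
#' distended/control). Total ERK1/2 intensities are lognormal and independent
#' of group; pERK intensities are lognormal around
#' `ratio_mean(group) * ERK`, so per-lane phospho/total ratios are lognormal
#' around the group ratio mean. The distension effects apply to pERK2 only.
#'
#' @param params [blot_sim_params()].
#' @return data.frame of class `blot_lanes`: `animal`, `temp_C`,
#'   `condition`, `perk1`, `perk2`, `erk1`, `erk2` (all intensities > 0).
#' @export
simulate_blot_lanes <- function(params = blot_sim_params()) {
  set.seed(derive_seed(params$seed, 104729L))
  grid <- expand.grid(condition = c("control", "distended"),
                      temp_C = c(37.5, 33.5), stringsAsFactors = FALSE)
  sdlog <- sqrt(log(1 + params$lane_cv^2))
  rows <- list()
  animal <- 0L
  for (g in seq_len(nrow(grid))) {
    eff <- if (grid$condition[g] == "control") 1
           else if (grid$temp_C[g] == 37.5) params$distension_effect_37
           else params$distension_effect_33
    n <- params$n_per_group
    erk1 <- params$erk_mean * exp(rnorm(n, 0, sdlog))
    erk2 <- params$erk_mean * exp(rnorm(n, 0, sdlog))
    perk1 <- params$control_ratio_mean * erk1 * exp(rnorm(n, 0, sdlog))
    perk2 <- params$control_ratio_mean * eff * erk2 * exp(rnorm(n, 0, sdlog))
    rows[[g]] <- data.frame(animal = animal + seq_len(n),
                            temp_C = grid$temp_C[g],
                            condition = grid$condition[g],
                            perk1 = perk1, perk2 = perk2,
                            erk1 = erk1, erk2 = erk2)
    animal <- animal + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("blot_lanes", "data.frame")
  out
}
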