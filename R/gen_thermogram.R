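#' Specification of a synthetic PPC thermogram
#'
#' Emulates the pulse schedule of a pressure perturbation calorimetry scan:
#' a slow temperature ramp (default 0.1 C/min) with a pressurization pulse
#' at the start of every `pulse_interval_s` interval (default 600 s, i.e.
#' every 1 C) and the matching depressurization pulse half an interval
#' later, so events alternate up/down starting with up. Each pulse deposits
#' a thermal spike of known integrated area on top of a drifting baseline.
#'
#' @param t_start_C,t_end_C Ramp limits (C); defaults 7 and 62.
#' @param spike_areas Planted pulse heats: either a named numeric vector
#'   mapping up-pulse temperature (as `sprintf("%g", T)`) to the
#'   pressurization heat in microjoules, or a function of temperature.
#'   Up-pulse spikes carry the sign of the heat; down-pulse spikes mirror it.
#' @param pulse_interval_s Seconds between up-pulses (default 600).
#' @param heating_rate_C_per_min Ramp rate (default 0.1).
#' @param dp_bar Pulse magnitude (default 4 bar).
#' @param spike_model `"rect"`, `"gauss"` or `"expdecay"`.
#' @param rect_height_uW Rectangular spike height (microwatt); the duration
#'   is then `|area| / height`.
#' @param gauss_sd_s Gaussian spike sd (s).
#' @param expdecay_tau_s Exponential spike time constant (s).
#' @param baseline_drift_uW_per_C Linear baseline drift (microwatt per C).
#' @param baseline_offset_uW Baseline value at `t_start_C` (microwatt).
#' @param noise_sd_uW Gaussian measurement noise sd (microwatt).
#' @param sample_dt_s Sampling interval (s, default 1).
#' @param seed Integer seed.
#' @return An object of class `"thermogram_spec"`.
#' @export
thermogram_spec <- function(spike_areas, t_start_C = 7, t_end_C = 62,
                            pulse_interval_s = 600,
                            heating_rate_C_per_min = 0.1, dp_bar = 4,
                            spike_model = c("gauss", "rect", "expdecay"),
                            rect_height_uW = 10, gauss_sd_s = 8,
                            expdecay_tau_s = 10,
                            baseline_drift_uW_per_C = 0,
                            baseline_offset_uW = 0, noise_sd_uW = 0,
                            sample_dt_s = 1, seed = 1L) {
  stopifnot(t_start_C < t_end_C, pulse_interval_s > 0,
            heating_rate_C_per_min > 0, dp_bar > 0, sample_dt_s > 0)
  structure(list(spike_areas = spike_areas, t_start_C = t_start_C,
                 t_end_C = t_end_C, pulse_interval_s = pulse_interval_s,
                 heating_rate_C_per_min = heating_rate_C_per_min,
                 dp_bar = dp_bar, spike_model = match.arg(spike_model),
                 rect_height_uW = rect_height_uW, gauss_sd_s = gauss_sd_s,
                 expdecay_tau_s = expdecay_tau_s,
                 baseline_drift_uW_per_C = baseline_drift_uW_per_C,
                 baseline_offset_uW = baseline_offset_uW,
                 noise_sd_uW = noise_sd_uW, sample_dt_s = sample_dt_s,
                 seed = as.integer(seed)),
            class = "thermogram_spec")
}

# scheduled up-pulse temperatures for a spec
pulse_schedule <- function(spec) {
  rate_s <- spec$heating_rate_C_per_min / 60
  n <- floor((spec$t_end_C - spec$t_start_C) /
               (rate_s * spec$pulse_interval_s)) + 1L
  k <- seq_len(n) - 1L
  data.frame(time_s = k * spec$pulse_interval_s,
             temp_C = spec$t_start_C + k * rate_s * spec$pulse_interval_s)
}

lookup_area <- function(spike_areas, temp) {
  if (is.function(spike_areas))
    return(vapply(temp, function(tt) as.numeric(spike_areas(tt)), numeric(1)))
  key <- sprintf("%g", temp)
  miss <- !(key %in% names(spike_areas))
  if (any(miss))
    stop("no spike area defined for scheduled pulse temperature(s): ",
         paste(key[miss], collapse = ", "))
  unname(spike_areas[key])
}

#' Generate a synthetic thermogram with planted pulse areas
#'
#' The integrated area of every spike equals the requested heat exactly
#' (before noise): rectangular spikes span an integer number of samples,
#' and the smooth shapes decay to negligible mass within the half-interval
#' between events. Exothermic pressurization follows the positive-up
#' convention: the up-pulse spike carries the sign of the planted heat and
#' the paired down-pulse mirrors it.
#'
#' @param spec A [thermogram_spec()].
#' @return A [thermogram()].
#' @export
gen_thermogram <- function(spec) {
  stopifnot(inherits(spec, "thermogram_spec"))
  sched <- pulse_schedule(spec)
  areas <- lookup_area(spec$spike_areas, sched$temp_C)
  rate_s <- spec$heating_rate_C_per_min / 60
  # half-interval lead-in so the first event has a pre-baseline window
  lead_in <- spec$pulse_interval_s / 2
  total <- lead_in + nrow(sched) * spec$pulse_interval_s
  t <- seq(0, total, by = spec$sample_dt_s)
  temp <- spec$t_start_C + rate_s * (t - lead_in)
  power <- spec$baseline_offset_uW +
    spec$baseline_drift_uW_per_C * (temp - spec$t_start_C)

  ev_time <- as.numeric(rbind(lead_in + sched$time_s,
                              lead_in + sched$time_s +
                                spec$pulse_interval_s / 2))
  ev_dir <- rep(c("up", "down"), nrow(sched))
  ev_area <- as.numeric(rbind(areas, -areas))

  for (i in seq_along(ev_time)) {
    power <- power + spike_profile(t, ev_time[i], ev_area[i], spec)
  }
  if (spec$noise_sd_uW > 0) {
    power <- power + withr::with_seed(
      spec$seed, stats::rnorm(length(t), sd = spec$noise_sd_uW))
  }
  thermogram(
    samples = data.frame(time_s = t, temp_C = temp, power_uW = power),
    events = data.frame(time_s = ev_time, direction = ev_dir,
                        dp_bar = spec$dp_bar))
}

spike_profile <- function(t, t0, area, spec) {
  if (area == 0) return(numeric(length(t)))
  switch(spec$spike_model,
    rect = {
      h <- sign(area) * spec$rect_height_uW
      dur <- abs(area) / spec$rect_height_uW
      # active on (t0, t0 + dur]: trapezoidal integration from the event
      # start then recovers exactly height x duration on an aligned grid
      h * (t > t0 & t <= t0 + dur)
    },
    gauss = {
      # centred 4 sd after the event so the leading tail is negligible
      area * stats::dnorm(t, mean = t0 + 4 * spec$gauss_sd_s,
                          sd = spec$gauss_sd_s)
    },
    expdecay = {
      out <- numeric(length(t))
      sel <- t >= t0
      out[sel] <- area / spec$expdecay_tau_s *
        exp(-(t[sel] - t0) / spec$expdecay_tau_s)
      out
    })
}
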