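#' Integrate the thermal spike of one pressure event
#'
#' Baseline-corrected trapezoidal integration of the differential power
#' around a pressure pulse. The baseline is interpolated linearly between
#' the medians of a pre-event window and a window just before the next
#' event (constant and spline alternatives are available). Integration runs
#' from the event start to the return to baseline — the first sample whose
#' excess stays within `2 * noise sd` of the baseline for
#' `settle_s` seconds — and is capped at the next event. The noise sd is
#' estimated as the sd of the detrended pre-event window; a floor of 1e-6
#' microwatt keeps the return test meaningful for noise-free input. A spike
#' still away from baseline at the cap is integrated to the cap and flagged
#' unreliable.
#'
#' @param tg A [thermogram()].
#' @param event Event row index into `tg$events`.
#' @param baseline_window_s Width of the pre/post baseline windows (s).
#' @param method Baseline model: `"linear"` (default), `"constant"` or
#'   `"spline"` (natural spline through both window medians).
#' @param settle_s Seconds the excess must stay within tolerance to count
#'   as returned to baseline.
#' @return List: `dq_uJ`, `temp_C` (sample temperature at event start),
#'   `direction`, `dp_bar`, `reliable`, `t_return_s`.
#' @export
integrate_pulse <- function(tg, event, baseline_window_s = 60,
                            method = c("linear", "constant", "spline"),
                            settle_s = 10) {
  stopifnot(inherits(tg, "thermogram"), event >= 1, event <= nrow(tg$events))
  method <- match.arg(method)
  s <- tg$samples
  ev <- tg$events[event, ]
  t0 <- ev$time_s
  t_next <- if (event < nrow(tg$events)) tg$events$time_s[event + 1L]
    else max(s$time_s)
  others <- tg$events$time_s[-event]
  pre_lo <- t0 - baseline_window_s
  if (any(others >= pre_lo & others < t0))
    stop("another event inside the pre-baseline window; events overlap")

  pre <- s[s$time_s >= pre_lo & s$time_s < t0, ]
  post <- s[s$time_s >= t_next - baseline_window_s & s$time_s < t_next, ]
  if (nrow(pre) < 3L || nrow(post) < 3L)
    stop("baseline windows too short around event ", event)
  bp <- c(stats::median(pre$time_s), stats::median(pre$power_uW))
  ba <- c(stats::median(post$time_s), stats::median(post$power_uW))
  # integration segment ends where the post-baseline window begins: that
  # window is by construction at baseline, and may already carry the
  # leading tail of the next event's spike
  seg <- s[s$time_s >= t0 & s$time_s < t_next - baseline_window_s, ]
  baseline <- switch(method,
    linear = bp[2] + (seg$time_s - bp[1]) * (ba[2] - bp[2]) / (ba[1] - bp[1]),
    constant = rep((bp[2] + ba[2]) / 2, nrow(seg)),
    spline = stats::spline(c(bp[1], ba[1]), c(bp[2], ba[2]), xout = seg$time_s,
                           method = "natural")$y)
  excess <- seg$power_uW - baseline
  # noise level from the detrended pre-window
  res <- stats::lm.fit(cbind(1, pre$time_s), pre$power_uW)$residuals
  tol <- max(2 * stats::sd(res), 1e-6)
  dt <- stats::median(diff(seg$time_s))
  k <- max(1L, ceiling(settle_s / dt))
  quiet <- abs(excess) <= tol
  # first index where `quiet` holds for k consecutive samples
  run <- stats::filter(as.numeric(quiet), rep(1, k), sides = 1)
  ret <- which(run == k)
  # settle must come at or after the spike extremum (">=" keeps the
  # degenerate zero-area spike, quiet everywhere, well-defined)
  ret <- ret[ret >= which.max(abs(excess))]
  if (length(ret)) {
    end <- ret[1]
    reliable <- TRUE
  } else {
    end <- nrow(seg)
    reliable <- FALSE
    warning(sprintf(
      "event %d: spike did not return to baseline before the next event; integral capped",
      event))
  }
  dq <- pracma::trapz(seg$time_s[1:end], excess[1:end])
  i0 <- which.min(abs(s$time_s - t0))
  list(dq_uJ = unname(dq), temp_C = s$temp_C[i0],
       direction = as.character(ev$direction), dp_bar = ev$dp_bar,
       reliable = reliable, t_return_s = seg$time_s[end])
}

#' Reduce a thermogram to a pressurization-heat series
#'
#' Integrates every annotated pressure event and assembles the per-event
#' heats into a temperature-ordered series. By default the series is
#' trimmed to the usable 9-61 C range, discarding the settling ends of the
#' scan.
#'
#' @param tg A [thermogram()].
#' @param trim Trim to `trim_range` (default `TRUE`).
#' @param trim_range Usable temperature range (C).
#' @param label Series label (e.g. a mole percentage).
#' @inheritParams integrate_pulse
#' @return An object of class `"deltaq_series"`: data frame with columns
#'   `temp_C`, `dq_uJ`, `direction`, `dp_bar`, `reliable`, plus attribute
#'   `label`.
#' @export
reduce_thermogram <- function(tg, trim = TRUE, trim_range = c(9, 61),
                              baseline_window_s = 60, method = "linear",
                              label = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  if (!nrow(tg$events)) stop("thermogram has no annotated pressure events")
  rows <- lapply(seq_len(nrow(tg$events)), function(i) {
    r <- integrate_pulse(tg, i, baseline_window_s = baseline_window_s,
                         method = method)
    data.frame(temp_C = r$temp_C, dq_uJ = r$dq_uJ, direction = r$direction,
               dp_bar = r$dp_bar, reliable = r$reliable)
  })
  out <- do.call(rbind, rows)
  eps <- 1e-9  # guard against float jitter in ramp temperatures
  if (trim) out <- out[out$temp_C >= trim_range[1] - eps &
                         out$temp_C <= trim_range[2] + eps, , drop = FALSE]
  out <- out[order(out$direction, out$temp_C), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("deltaq_series", "data.frame")
  out
}

#' Window gradient of the pressurization-heat series
#'
#' Ordinary least-squares slope of `dq/dp` versus temperature over a
#' window — the pressure derivative of the mixture's average heat capacity
#' over that window, natively in microjoule per bar per kelvin. Entries
#' with `R^2 < 0.8` are flagged low-confidence rather than dropped.
#'
#' @param series A `"deltaq_series"` (or data frame with `temp_C`, `dq_uJ`,
#'   `dp_bar`).
#' @param window `(T_low, T_high)` in C; default `c(9, 35)`.
#' @param direction Pulse direction to use (default `"up"`); `NULL` uses all.
#' @return An object of class `"gradient_result"`: list with `slope_uJ_bar_K`,
#'   `intercept_uJ_bar`, `r_squared`, `n_points`, `window`, `low_confidence`.
#' @export
window_gradient <- function(series, window = c(9, 35), direction = "up") {
  stopifnot(window[1] < window[2])
  d <- as.data.frame(series)
  if (!is.null(direction) && "direction" %in% names(d))
    d <- d[d$direction == direction, , drop = FALSE]
  d <- d[d$temp_C >= window[1] & d$temp_C <= window[2], , drop = FALSE]
  if (nrow(d) < 3L)
    stop("fewer than 3 points in the gradient window [", window[1], ", ",
         window[2], "] C")
  y <- d$dq_uJ / d$dp_bar
  fit <- stats::lm(y ~ d$temp_C)
  sst <- sum((y - mean(y))^2)
  # define R^2 = 1 for an exactly constant response (zero slope, zero error)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope_uJ_bar_K = unname(stats::coef(fit)[2]),
                 intercept_uJ_bar = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = nrow(d), window = window,
                 low_confidence = r2 < 0.8),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf(
    "gradient over %g-%g C: %.3f uJ/(bar K) (R^2 = %.3f, n = %d%s)\n",
    x$window[1], x$window[2], x$slope_uJ_bar_K, x$r_squared, x$n_points,
    if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' Deviation from linear mixing of pressurization heats
#'
#' For each composition, the difference between the measured heat and the
#' straight line connecting the pure-water (0 mol%) and pure-alcohol
#' (100 mol%) endpoints: an excess-property analogue. Endpoints evaluate to
#' exactly zero; both must be present.
#'
#' @param dq_by_composition Data frame with columns `mole_percent` and
#'   `dq_uJ`, one row per composition at a common temperature.
#' @return The input with an added `ddq_uJ` column.
#' @export
delta_delta_q <- function(dq_by_composition) {
  d <- as.data.frame(dq_by_composition)
  stopifnot(all(c("mole_percent", "dq_uJ") %in% names(d)))
  i0 <- which(d$mole_percent == 0)
  i1 <- which(d$mole_percent == 100)
  if (!length(i0) || !length(i1))
    stop("both endpoint compositions (0 and 100 mol%) are required")
  q0 <- d$dq_uJ[i0[1]]
  q1 <- d$dq_uJ[i1[1]]
  f <- d$mole_percent / 100
  d$ddq_uJ <- d$dq_uJ - ((1 - f) * q0 + f * q1)
  d
}
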