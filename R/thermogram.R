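#' Differential-power thermogram with pressure-event annotations
#'
#' The raw record of a pressure perturbation calorimetry (PPC) scan: a time
#' series of differential power between sample and reference cells along a
#' slow temperature ramp, plus the schedule of pressure events (pulses)
#' applied to both cells.
#'
#' @param samples Data frame with columns `time_s`, `temp_C`, `power_uW`;
#'   times strictly increasing.
#' @param events Data frame with columns `time_s`, `direction`
#'   (`"up"`/`"down"`), `dp_bar` (> 0); event times must lie inside the
#'   sampled time range.
#' @return An object of class `"thermogram"`.
#' @export
thermogram <- function(samples, events) {
  samples <- as.data.frame(samples)
  events <- as.data.frame(events)
  need_s <- c("time_s", "temp_C", "power_uW")
  need_e <- c("time_s", "direction", "dp_bar")
  if (!all(need_s %in% names(samples)))
    stop("samples needs columns: ", paste(need_s, collapse = ", "))
  if (!all(need_e %in% names(events)))
    stop("events needs columns: ", paste(need_e, collapse = ", "))
  dt <- diff(samples$time_s)
  if (any(dt <= 0)) {
    stop("sample times must be strictly increasing; first offending row: ",
         which(dt <= 0)[1] + 1L)
  }
  if (!all(events$direction %in% c("up", "down")))
    stop("event direction must be 'up' or 'down'")
  if (any(events$dp_bar <= 0)) stop("event magnitudes must be positive")
  rng <- range(samples$time_s)
  if (nrow(events) &&
      any(events$time_s < rng[1] | events$time_s > rng[2]))
    stop("event times must lie within the sampled time range")
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(samples = samples, events = events), class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf(
    "thermogram: %d samples, %.0f-%.0f s, %.2f-%.2f C, %d pressure events\n",
    nrow(x$samples), min(x$samples$time_s), max(x$samples$time_s),
    min(x$samples$temp_C), max(x$samples$temp_C), nrow(x$events)))
  invisible(x)
}

#' Read / write a thermogram CSV pair
#'
#' `read_thermogram_csv` expects a CSV with columns `time_s`, `temp_C`,
#' `power_uW` and a sidecar events table `<path basename>_events.csv`
#' (columns `time_s`, `direction`, `dp_bar`); alternatively `events_path`
#' names the sidecar explicitly. `write_thermogram_csv` emits the pair.
#'
#' @param path Samples CSV path.
#' @param events_path Events CSV path (default: derived sidecar name).
#' @return A [thermogram()]; the writer returns `path` invisibly.
#' @export
read_thermogram_csv <- function(path, events_path = NULL) {
  if (is.null(events_path)) events_path <- sidecar_events_path(path)
  samples <- utils::read.csv(path)
  events <- if (file.exists(events_path)) utils::read.csv(events_path)
    else data.frame(time_s = numeric(0), direction = character(0),
                    dp_bar = numeric(0))
  thermogram(samples, events)
}

#' @rdname read_thermogram_csv
#' @param tg A [thermogram()].
#' @export
write_thermogram_csv <- function(tg, path, events_path = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  if (is.null(events_path)) events_path <- sidecar_events_path(path)
  utils::write.csv(tg$samples, path, row.names = FALSE)
  utils::write.csv(tg$events, events_path, row.names = FALSE)
  invisible(path)
}

sidecar_events_path <- function(path) {
  file.path(dirname(path),
            paste0(tools::file_path_sans_ext(basename(path)), "_events.",
                   tools::file_ext(path)))
}
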