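# Running-wheel kinematics: absolute-encoder voltage -> distances -> bouts.

#' Wheel calibration
#'
#' The wheel's absolute rotary encoder reports angular position as a voltage
#' in `[0, v_max]` that wraps at a full revolution. The calibration constant
#' converts a voltage change to meters travelled around the circumference:
#' the default 0.07690168 m/V implies a circumference of about 0.3845 m.
#'
#' @param meters_per_volt Meters of circumference per volt of encoder change.
#' @param v_max Encoder full-scale voltage (one revolution).
#' @param wrap Wrap policy: `"minimal"` takes the minimal-magnitude circular
#'   displacement for each voltage step (so `|dv| <= v_max / 2`), `"none"`
#'   uses raw differences. At full running speed the encoder moves about half
#'   a revolution between 16 Hz samples, so half a revolution is the largest
#'   per-sample motion that can be recovered at all; faster motion is aliased.
#' @return An object of class `wheel_calibration`.
#' @export
wheel_calibration <- function(meters_per_volt = 0.07690168, v_max = 5,
                              wrap = c("minimal", "none")) {
  wrap <- match.arg(wrap)
  stopifnot(meters_per_volt > 0, v_max > 0)
  structure(list(meters_per_volt = meters_per_volt, v_max = v_max, wrap = wrap),
            class = "wheel_calibration")
}

#' @export
print.wheel_calibration <- function(x, ...) {
  cat(sprintf("<wheel_calibration> %.8f m/V, %g V full scale, wrap = %s\n",
              x$meters_per_volt, x$v_max, x$wrap))
  invisible(x)
}

#' Decode per-step wheel displacements from encoder voltage
#'
#' Converts consecutive voltage samples into unsigned per-step distances.
#' Under the `"minimal"` wrap policy each raw voltage change is mapped to the
#' minimal-magnitude circular displacement (ties at exactly half a revolution
#' resolve to forward motion; the distance is unsigned either way), so a
#' 4.9 V to 0.1 V step reads as 0.2 V of forward motion rather than 4.8 V
#' backwards.
#'
#' @param samples Tibble with columns `t`, `v` (see [read_analog_csv()]).
#' @param cal A [wheel_calibration()].
#' @param tol Voltage tolerance outside `[0, v_max]` before erroring.
#' @return Tibble with columns `t` (time of the later sample of each step)
#'   and `d` (meters, `>= 0`), carrying attribute `t_origin` (first sample's
#'   time) used to anchor accumulation windows. A single sample yields an
#'   empty result.
#' @export
decode_displacement <- function(samples, cal = wheel_calibration(), tol = 1e-6) {
  stopifnot(inherits(cal, "wheel_calibration"), all(c("t", "v") %in% names(samples)))
  v <- samples$v
  t <- samples$t
  if (length(t) > 1 && is.unsorted(t)) stop("samples must be sorted by time", call. = FALSE)
  bad <- which(v < -tol | v > cal$v_max + tol)
  if (length(bad) > 0) {
    stop(sprintf("voltage %.4f V at t = %.3f outside [0, %g] V",
                 v[bad[1]], t[bad[1]], cal$v_max), call. = FALSE)
  }
  out <- tibble::tibble(t = numeric(), d = numeric())
  if (length(v) >= 2) {
    dv <- diff(v)
    if (cal$wrap == "minimal") {
      half <- cal$v_max / 2
      dv <- ((dv + half) %% cal$v_max) - half
      dv[dv == -half] <- half  # tie at half a revolution resolves forward
    }
    out <- tibble::tibble(t = t[-1], d = abs(dv) * cal$meters_per_volt)
  }
  attr(out, "t_origin") <- if (length(t) > 0) t[1] else NA_real_
  out
}

#' Accumulate displacements into fixed windows
#'
#' Sums per-step distances over tumbling windows (default 1 s) anchored at
#' the first sample of the trace, the last window running to the end of the
#' data. Windows with zero displacement emit no measurement, so the output
#' is sparse in time; total distance is conserved exactly.
#'
#' @param displacements Tibble from [decode_displacement()] (columns `t`, `d`).
#' @param window Window length in seconds; default 1.
#' @param t_origin Window anchor; defaults to the `t_origin` attribute left
#'   by [decode_displacement()], else the first displacement time.
#' @return Tibble with columns `t` (window end time) and `d` (meters in the
#'   window, `> 0`).
#' @export
accumulate_windows <- function(displacements, window = 1, t_origin = NULL) {
  stopifnot(window > 0, all(c("t", "d") %in% names(displacements)))
  if (nrow(displacements) == 0) return(tibble::tibble(t = numeric(), d = numeric()))
  t <- displacements$t
  if (is.unsorted(t)) stop("displacements must be sorted by time", call. = FALSE)
  if (is.null(t_origin)) t_origin <- attr(displacements, "t_origin", exact = TRUE)
  if (is.null(t_origin) || is.na(t_origin)) t_origin <- t[1]
  # displacement timestamps are interval ends: a step stamped exactly on a
  # window boundary carries motion from inside that window, so windows are
  # left-open/right-closed in displacement time
  idx <- ceiling((t - t_origin) / window) - 1
  idx[idx < 0] <- 0
  agg <- rowsum(displacements$d, group = idx)
  win <- as.numeric(rownames(agg))
  keep <- agg[, 1] > 0
  tibble::tibble(t = t_origin + (win[keep] + 1) * window,
                 d = unname(agg[keep, 1]))
}

#' Segment distance measurements into running bouts
#'
#' A running bout (event) is a maximal run of distance measurements whose
#' inter-timestamp gaps do not exceed `max_gap`; the boundary is inclusive,
#' so a gap of exactly 2 s still joins one bout. Speed is distance over the
#' bout span `t_end - t_start`, floored at one window so a single-measurement
#' bout has a defined speed.
#'
#' @param measurements Tibble from [accumulate_windows()] (columns `t`, `d`),
#'   sorted by `t`.
#' @param max_gap Maximal joining gap in seconds; default 2.
#' @param min_duration Duration floor in seconds (one accumulation window).
#' @return Tibble with columns `t_start`, `t_end`, `n_meas`, `distance_m`,
#'   `speed_mps`.
#' @export
segment_bouts <- function(measurements, max_gap = 2, min_duration = 1) {
  stopifnot(max_gap >= 0, all(c("t", "d") %in% names(measurements)))
  if (nrow(measurements) == 0) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_meas = integer(), distance_m = numeric(),
                          speed_mps = numeric()))
  }
  t <- measurements$t
  if (is.unsorted(t)) stop("measurements must be sorted by time", call. = FALSE)
  bout_id <- cumsum(c(1, as.integer(diff(t) > max_gap)))
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(bout_id, t, d = measurements$d), bout_id),
    t_start = t[1], t_end = t[dplyr::n()], n_meas = dplyr::n(),
    distance_m = sum(d), .groups = "drop"
  ) |>
    dplyr::mutate(speed_mps = distance_m / pmax(t_end - t_start, min_duration)) |>
    dplyr::select(-bout_id)
}

#' Intervals between successive bout starts
#'
#' @param bouts Tibble from [segment_bouts()], sorted by `t_start`.
#' @return Numeric vector of `n - 1` start-to-start intervals (seconds);
#'   empty for fewer than two bouts.
#' @export
bout_intervals <- function(bouts) {
  stopifnot("t_start" %in% names(bouts))
  if (nrow(bouts) > 1 && is.unsorted(bouts$t_start)) {
    stop("bouts must be sorted by t_start", call. = FALSE)
  }
  diff(bouts$t_start)
}

#' Cumulative distance series
#'
#' Running prefix sum of a binned distance series. Masked bins contribute 0
#' to the total and remain masked, but carry the running total so the curve
#' stays plottable.
#'
#' @param x An [binned_series()] of distances (minute or hour bins).
#' @return An `hc_binned` series; the final value equals the sum of unmasked
#'   values and the output is non-decreasing.
#' @export
cumulative_distance <- function(x) {
  w <- bin_width(x)
  binned_series(x$bin_start, cumsum(ifelse(x$masked, 0, x$value)),
                masked = x$masked, bin_width = w)
}

#' Flag non-physiological wheel activity
#'
#' Flags (never deletes) hourly distance bins that look non-physiological:
#' spikes above `spike_max_m` meters in one hour, or sustained light-phase
#' running -- `light_run_min` or more consecutive nonzero hours all in the
#' light phase. Masking flagged hours is an explicit caller action (see
#' [mask_hours()]), keeping a human-review seam in the QC loop.
#'
#' @param hourly An hourly [binned_series()] of distances.
#' @param schedule A [light_schedule()].
#' @param spike_max_m Spike threshold in meters/hour; default 700 (about
#'   twice the busiest plausible hour for a mouse running ~7 km/day).
#' @param light_run_min Minimal run length (hours) of consecutive nonzero
#'   light-phase bins to flag; default 12, i.e. running through the entire
#'   light phase.
#' @return Tibble with columns `bin` (1-based index), `bin_start`, `value`,
#'   `reason` (`"spike"` or `"light_run"`); zero rows when nothing is flagged.
#' @export
flag_nonphysiological <- function(hourly, schedule, spike_max_m = 700,
                                  light_run_min = 12) {
  stopifnot(bin_width(hourly) == 3600)
  light <- is_light_phase(hourly$bin_start, schedule)
  spike <- which(!hourly$masked & hourly$value > spike_max_m)
  active_light <- !hourly$masked & light & hourly$value > 0
  runs <- rle(active_light)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  light_run <- integer()
  for (k in seq_along(runs$lengths)) {
    if (runs$values[k] && runs$lengths[k] >= light_run_min) {
      light_run <- c(light_run, seq(starts[k], ends[k]))
    }
  }
  out <- dplyr::bind_rows(
    tibble::tibble(bin = spike, reason = "spike"),
    tibble::tibble(bin = light_run, reason = "light_run")
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(bin = integer(), bin_start = numeric(),
                          value = numeric(), reason = character()))
  }
  out$bin_start <- hourly$bin_start[out$bin]
  out$value <- hourly$value[out$bin]
  dplyr::arrange(out[, c("bin", "bin_start", "value", "reason")], bin, reason)
}
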