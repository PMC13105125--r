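# Time conventions, raw CSV dialects, and generic binning.
#
# All timestamps are POSIX seconds (numeric, fractional allowed) and all
# clock arithmetic is pure UTC: zeitgeber conversion never consults the
# system timezone or daylight-saving rules.

#' Light schedule
#'
#' Describes the photoperiod that anchors zeitgeber time (ZT). ZT0 is
#' lights-on and, under the default 12:12 cycle, ZT12 is lights-off.
#'
#' @param lights_on Time of day lights turn on, UTC. Either a `"HH:MM"` /
#'   `"HH:MM:SS"` string or seconds since midnight UTC. Default `"05:00"`.
#' @param photoperiod_h Hours of light per cycle; default 12.
#' @param period_h Cycle length in hours; fixed at 24.
#'
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule("05:00", 12)
#' posix_to_zt(18000, sched) # 05:00:00 UTC is ZT0
#' @export
light_schedule <- function(lights_on = "05:00", photoperiod_h = 12, period_h = 24) {
  if (is.character(lights_on)) {
    parts <- as.numeric(strsplit(lights_on, ":", fixed = TRUE)[[1]])
    if (any(is.na(parts)) || length(parts) < 2 || length(parts) > 3) {
      stop("`lights_on` must be 'HH:MM', 'HH:MM:SS', or seconds since midnight UTC",
           call. = FALSE)
    }
    lights_on <- parts[1] * 3600 + parts[2] * 60 + if (length(parts) == 3) parts[3] else 0
  }
  stopifnot(period_h == 24, photoperiod_h > 0, photoperiod_h <= period_h,
            lights_on >= 0, lights_on < 86400)
  structure(
    list(lights_on_utc = lights_on, photoperiod_h = photoperiod_h, period_h = period_h),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> lights on %02d:%02d:%02d UTC, %g:%g L:D\n",
              x$lights_on_utc %/% 3600, (x$lights_on_utc %% 3600) %/% 60,
              round(x$lights_on_utc %% 60),
              x$photoperiod_h, x$period_h - x$photoperiod_h))
  invisible(x)
}

#' Convert POSIX time to zeitgeber time
#'
#' @param t Numeric vector of POSIX seconds.
#' @param schedule A [light_schedule()].
#'
#' @return Numeric vector of ZT hours in `[0, 24)`.
#' @examples
#' sched <- light_schedule("05:00")
#' posix_to_zt(c(18000, 18000 + 12 * 3600), sched) # ZT0, ZT12
#' @export
posix_to_zt <- function(t, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  (((t %% 86400) - schedule$lights_on_utc) / 3600) %% 24
}

#' @describeIn posix_to_zt Integer ZT hour bin (0--23) containing `t`.
#' @export
zt_hour <- function(t, schedule) {
  floor(posix_to_zt(t, schedule)) %% 24
}

#' @describeIn posix_to_zt TRUE when `t` falls in the light phase
#'   (ZT in `[0, photoperiod_h)`).
#' @export
is_light_phase <- function(t, schedule) {
  posix_to_zt(t, schedule) < schedule$photoperiod_h
}

#' Experiment day index
#'
#' Day 1 starts at `t0` (conventionally a lights-on instant) and each day is
#' exactly 86400 s.
#'
#' @param t POSIX seconds.
#' @param t0 POSIX seconds of the start of day 1.
#' @return Integer day index (values before `t0` give indices < 1).
#' @export
experiment_day <- function(t, t0) {
  as.integer(floor((t - t0) / 86400)) + 1L
}

# ---- channel map -----------------------------------------------------------

#' Operant channel map
#'
#' The digital event log carries eight Boolean channels: four nose-poke
#' beambreaks (one per dispenser) and the four mirrored dispense-command
#' lines. Positions 1 and 2 are the two physical dispenser locations per
#' medium; which content (sucrose vs regular water, fatty vs regular food)
#' sits at which position on a given day is resolved by the swap schedule,
#' not by the channel map.
#'
#' @return A tibble with columns `channel` (1--8), `name`, `role`
#'   (`"beambreak"` or `"dispense"`), `medium` (`"water"`/`"food"`) and
#'   `position` (1 or 2).
#' @export
channel_map <- function() {
  tibble::tibble(
    channel  = 1:8,
    name     = c("bb_water_p1", "bb_water_p2", "bb_food_p1", "bb_food_p2",
                 "disp_water_p1", "disp_water_p2", "disp_food_p1", "disp_food_p2"),
    role     = rep(c("beambreak", "dispense"), each = 4),
    medium   = rep(rep(c("water", "food"), each = 2), 2),
    position = rep(c(1L, 2L), 4)
  )
}

# ---- raw CSV dialects ------------------------------------------------------

# Both device logs are event-driven: a line is appended whenever any pin
# changes, carrying the full pin state next to a POSIX timestamp.

digital_cols <- function() c("t", channel_map()$name)

detect_header <- function(first_line) {
  first_field <- strsplit(first_line, ",", fixed = TRUE)[[1]][1]
  is.na(suppressWarnings(as.numeric(first_field)))
}

#' Read a digital (beambreak/dispense) event CSV
#'
#' Lines hold a POSIX timestamp followed by the 0/1 state of all eight
#' channels (see [channel_map()]); a line exists only when at least one
#' state changed. A header row is auto-detected. Rows sharing a timestamp
#' are collapsed keeping the last state.
#'
#' @param path Path to the CSV.
#' @return A tibble with numeric `t` plus eight logical channel columns,
#'   sorted by `t`.
#' @seealso [write_digital_csv()], [rising_edges()]
#' @export
read_digital_csv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  empty <- tibble::as_tibble(c(
    list(t = numeric()),
    stats::setNames(rep(list(logical()), 8), channel_map()$name)
  ))
  if (length(lines) == 0) return(empty)
  skip <- detect_header(lines[1])
  body <- if (skip) lines[-1] else lines
  if (length(body) == 0) return(empty)
  fields <- strsplit(body, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != 9)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of '%s': expected 9 fields, got %d",
                 bad[1] + skip, path, n_fields[bad[1]]), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 9, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    stop(sprintf("malformed row at line %d of '%s': non-numeric field",
                 bad + skip, path), call. = FALSE)
  }
  t <- mat[, 1]
  if (is.unsorted(t)) {
    i <- which(diff(t) < 0)[1]
    stop(sprintf("non-monotone timestamps in '%s': %.6f followed by %.6f",
                 path, t[i], t[i + 1]), call. = FALSE)
  }
  keep <- c(t[-1] != t[-length(t)], TRUE)  # duplicates: keep last
  out <- tibble::as_tibble(c(
    list(t = t[keep]),
    stats::setNames(lapply(2:9, function(j) mat[keep, j] != 0), channel_map()$name)
  ))
  out
}

#' Write a digital event CSV
#'
#' Timestamps are written with millisecond precision; the read/write round
#' trip is lossless at that resolution.
#'
#' @param events Tibble as returned by [read_digital_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_digital_csv <- function(events, path) {
  stopifnot(all(digital_cols() %in% names(events)))
  states <- vapply(channel_map()$name,
                   function(nm) as.integer(events[[nm]]), integer(nrow(events)))
  if (nrow(events) == 1) states <- matrix(states, nrow = 1)
  body <- if (nrow(events) == 0) character() else {
    paste(sprintf("%.3f", events$t),
          apply(states, 1, paste, collapse = ","), sep = ",")
  }
  readr::write_lines(c(paste(digital_cols(), collapse = ","), body), path)
  invisible(path)
}

#' Read an analog (wheel encoder voltage) CSV
#'
#' Lines hold a POSIX timestamp and the encoder voltage in `[0, 5]` V,
#' written on change at a nominal 16 Hz. Timestamps are authoritative;
#' the nominal rate is not enforced.
#'
#' @param path Path to the CSV.
#' @return A tibble with numeric columns `t` and `v`, sorted by `t`.
#' @export
read_analog_csv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  if (length(lines) == 0) return(tibble::tibble(t = numeric(), v = numeric()))
  skip <- detect_header(lines[1])
  body <- if (skip) lines[-1] else lines
  if (length(body) == 0) return(tibble::tibble(t = numeric(), v = numeric()))
  fields <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of '%s'", bad[1] + skip, path), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 2, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    stop(sprintf("malformed row at line %d of '%s': non-numeric field",
                 bad + skip, path), call. = FALSE)
  }
  t <- mat[, 1]
  if (is.unsorted(t)) {
    i <- which(diff(t) < 0)[1]
    stop(sprintf("non-monotone timestamps in '%s': %.6f followed by %.6f",
                 path, t[i], t[i + 1]), call. = FALSE)
  }
  keep <- c(t[-1] != t[-length(t)], TRUE)
  tibble::tibble(t = t[keep], v = mat[keep, 2])
}

#' Write an analog voltage CSV
#'
#' @param samples Tibble with columns `t`, `v`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analog_csv <- function(samples, path) {
  stopifnot(all(c("t", "v") %in% names(samples)))
  body <- if (nrow(samples) == 0) character() else {
    # 4 decimals carry the encoder's 1/16 s sample grid exactly
    sprintf("%.4f,%.6f", samples$t, samples$v)
  }
  readr::write_lines(c("t,v", body), path)
  invisible(path)
}

#' Rising edges of a digital channel
#'
#' Extracts discrete event times (beambreaks, dispense commands) from the
#' state-snapshot log: every false-to-true transition on the requested
#' channel. A channel already true on the first record counts as one edge at
#' that record's time -- the change happened before logging started.
#'
#' @param events Tibble from [read_digital_csv()].
#' @param channel Channel name (see [channel_map()]) or 1-based index 1--8.
#' @return Numeric vector of event times (POSIX seconds).
#' @export
rising_edges <- function(events, channel) {
  cm <- channel_map()
  if (is.character(channel)) {
    if (!channel %in% cm$name) {
      stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
    }
    nm <- channel
  } else {
    if (!is.numeric(channel) || length(channel) != 1 ||
        channel < 1 || channel > 8 || channel != as.integer(channel)) {
      stop("`channel` must be a channel name or an integer in 1..8", call. = FALSE)
    }
    nm <- cm$name[channel]
  }
  s <- events[[nm]]
  if (length(s) == 0) return(numeric())
  rising <- s & !c(FALSE, s[-length(s)])
  events$t[rising]
}

# ---- binned series ---------------------------------------------------------

#' Binned series
#'
#' A tibble of contiguous half-open bins `[bin_start, bin_start + width)`
#' with a per-bin exclusion mask. Absent data is a value of 0 with
#' `masked = FALSE`; excluded (QC-failed) data keeps its slot but is
#' `masked = TRUE` and carries `NA` downstream semantics.
#'
#' @param bin_start Numeric vector of bin left edges (POSIX seconds),
#'   strictly increasing with constant spacing `bin_width`.
#' @param value Numeric per-bin values.
#' @param masked Logical per-bin exclusion flags.
#' @param bin_width Bin width in seconds (60, 3600 or 86400).
#' @return A tibble of class `hc_binned` with attribute `bin_width`.
#' @export
binned_series <- function(bin_start, value, masked = rep(FALSE, length(value)),
                          bin_width) {
  stopifnot(length(bin_start) == length(value), length(masked) == length(value),
            bin_width %in% c(60, 3600, 86400))
  if (length(bin_start) > 1 && any(abs(diff(bin_start) - bin_width) > 1e-6)) {
    stop("bins must be contiguous with constant width", call. = FALSE)
  }
  out <- tibble::tibble(bin_start = as.numeric(bin_start),
                        value = as.numeric(value),
                        masked = as.logical(masked))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("hc_binned", class(out))
  out
}

#' @describeIn binned_series Bin width (seconds) of a binned series.
#' @param x An `hc_binned` series.
#' @export
bin_width <- function(x) {
  w <- attr(x, "bin_width", exact = TRUE)
  if (is.null(w)) stop("not a binned series (missing bin_width)", call. = FALSE)
  w
}

#' @export
print.hc_binned <- function(x, ...) {
  cat(sprintf("<hc_binned> width %ds, %d bins, %d masked\n",
              as.integer(bin_width(x)), nrow(x), sum(x$masked)))
  NextMethod()
}

check_span <- function(width, start, end) {
  stopifnot(width %in% c(60, 3600, 86400))
  if (end <= start) stop("span must be non-empty", call. = FALSE)
  if (abs((end - start) %% width) > 1e-9) {
    stop(sprintf("span [%g, %g) is not aligned to the %g s bin width",
                 start, end, width), call. = FALSE)
  }
}

#' Bin event times into counts
#'
#' Bins are half-open `[l, r)`: an event exactly on a boundary belongs to
#' the later bin. Bins with no events are present with count 0, so the
#' series has no gaps.
#'
#' @param times Numeric event times (POSIX seconds); need not be sorted.
#' @param width Bin width in seconds: 60, 3600 or 86400.
#' @param start,end Span `[start, end)`; `end - start` must be a multiple
#'   of `width`. Events outside the span are dropped.
#' @return An [binned_series()] of counts.
#' @examples
#' b <- bin_counts(c(10, 20, 3700), 3600, 0, 3 * 3600)
#' b$value # 2, 1, 0
#' @export
bin_counts <- function(times, width, start, end) {
  check_span(width, start, end)
  n <- as.integer(round((end - start) / width))
  idx <- floor((times - start) / width)
  idx <- idx[idx >= 0 & idx < n]
  counts <- tabulate(idx + 1L, nbins = n)
  binned_series(start + (seq_len(n) - 1) * width, counts, bin_width = width)
}

#' Bin weighted events into sums
#'
#' Like [bin_counts()] but each event carries a weight (e.g. meters moved in
#' a 1-s window) and bins hold weight sums.
#'
#' @inheritParams bin_counts
#' @param values Numeric weights, one per time.
#' @return An [binned_series()] of sums.
#' @export
bin_sum <- function(times, values, width, start, end) {
  stopifnot(length(times) == length(values))
  check_span(width, start, end)
  n <- as.integer(round((end - start) / width))
  idx <- floor((times - start) / width)
  keep <- idx >= 0 & idx < n
  sums <- numeric(n)
  if (any(keep)) {
    agg <- rowsum(values[keep], group = idx[keep])
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  binned_series(start + (seq_len(n) - 1) * width, sums, bin_width = width)
}

#' Annotate a binned series with zeitgeber time
#'
#' @param x An [binned_series()].
#' @param schedule A [light_schedule()].
#' @return `x` with added columns `zt_h` (ZT of the bin start) and `light`
#'   (TRUE in the light phase).
#' @export
add_zt <- function(x, schedule) {
  w <- bin_width(x)
  x$zt_h <- posix_to_zt(x$bin_start, schedule)
  x$light <- is_light_phase(x$bin_start, schedule)
  attr(x, "bin_width") <- w
  x
}
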