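# Consummatory event processing: dispense refractory logic, QC flagging,
# masking, and multi-scale aggregation.

#' Dispense controller (refractory timeout)
#'
#' Reproduces the dispenser firmware rule: the first nose poke dispenses,
#' and thereafter a poke dispenses only when at least `timeout` seconds have
#' passed since the last *dispense* (not the last poke). Intervals of
#' exactly `timeout` are allowed -- the rule forbids intervals of *less*
#' than the timeout. All pokes are recorded regardless; this function only
#' decides which ones trigger a dispense.
#'
#' @param poke_times Sorted numeric vector of poke (rising-edge) times.
#' @param timeout Refractory period in seconds; default 3.
#' @return Numeric vector of dispense times (a subset of `poke_times`).
#' @examples
#' dispense_controller(c(0, 2.9, 3.0)) # 0 and 3.0; the 2.9 s poke is refused
#' @export
dispense_controller <- function(poke_times, timeout = 3) {
  if (timeout < 0) stop("timeout must be non-negative", call. = FALSE)
  n <- length(poke_times)
  if (n == 0) return(numeric())
  if (is.unsorted(poke_times)) stop("poke_times must be sorted", call. = FALSE)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (poke_times[i] - last >= timeout) {
      keep[i] <- TRUE
      last <- poke_times[i]
    }
  }
  poke_times[keep]
}

#' Flag suspicious hourly counts
#'
#' Hours with more than `threshold` beambreaks are flagged for review
#' (dispenser clogging or leaking produce runaway counts). The comparison
#' is strict: exactly `threshold` is not flagged. Flagging never masks;
#' see [mask_hours()].
#'
#' @param hourly An hourly [binned_series()] of counts.
#' @param threshold Strict count threshold; default 500.
#' @return Tibble with columns `bin` (1-based), `bin_start`, `count`,
#'   `reason`.
#' @export
qc_flag_hours <- function(hourly, threshold = 500) {
  stopifnot(bin_width(hourly) == 3600)
  idx <- which(!hourly$masked & hourly$value > threshold)
  tibble::tibble(bin = idx, bin_start = hourly$bin_start[idx],
                 count = hourly$value[idx],
                 reason = rep(sprintf("count_gt_%g", threshold), length(idx)))
}

#' Mask hours in paired beambreak/dispense series
#'
#' Excluded data is removed in hour chunks: when an hour fails review, both
#' the beambreak and the dispense value for that hour are masked together
#' so the two series always share an exclusion pattern.
#'
#' @param beambreaks,dispenses Hourly [binned_series()] with identical
#'   binning.
#' @param hours Integer vector of 1-based bin indices to mask.
#' @return A list with elements `beambreaks` and `dispenses`, both masked at
#'   `hours`.
#' @export
mask_hours <- function(beambreaks, dispenses, hours) {
  wb <- bin_width(beambreaks); wd <- bin_width(dispenses)
  if (wb != wd || nrow(beambreaks) != nrow(dispenses) ||
      any(abs(beambreaks$bin_start - dispenses$bin_start) > 1e-6)) {
    stop("beambreak and dispense series must share identical binning", call. = FALSE)
  }
  if (length(hours) > 0 &&
      (any(hours < 1) || any(hours > nrow(beambreaks)) || any(hours != floor(hours)))) {
    stop("`hours` must be 1-based bin indices within the series", call. = FALSE)
  }
  beambreaks$masked[hours] <- TRUE
  dispenses$masked[hours] <- TRUE
  attr(beambreaks, "bin_width") <- wb
  attr(dispenses, "bin_width") <- wd
  list(beambreaks = beambreaks, dispenses = dispenses)
}

#' Aggregate an hourly series to days, weeks, or an hour-of-day profile
#'
#' Day and week aggregates are sums over member hours; masked hours are
#' excluded from the sum and reported alongside as `n_masked` (whole-day
#' exclusion is a caller decision, not automatic). The hour-of-day profile
#' is the mean over all unmasked instances of each ZT hour.
#'
#' @param hourly An hourly [binned_series()].
#' @param scale One of `"day"`, `"week"`, `"zt_profile"`.
#' @param schedule A [light_schedule()]; required for `"zt_profile"`.
#' @param t0 Start of experiment day 1 (POSIX seconds); defaults to the
#'   first bin start. Days and weeks are counted from `t0`.
#' @return A tibble: for `"day"`/`"week"`, columns `day`/`week`, `value`
#'   (sum over unmasked hours), `n_hours`, `n_masked`; for `"zt_profile"`,
#'   columns `zt_h` (0--23), `value` (mean), `n`.
#' @export
aggregate_series <- function(hourly, scale = c("day", "week", "zt_profile"),
                             schedule = NULL, t0 = NULL) {
  scale <- match.arg(scale)
  stopifnot(bin_width(hourly) == 3600)
  if (is.null(t0)) t0 <- hourly$bin_start[1]
  df <- tibble::as_tibble(hourly)
  if (scale == "zt_profile") {
    if (is.null(schedule)) stop("`schedule` is required for the ZT profile", call. = FALSE)
    df$zt_h <- as.integer(zt_hour(df$bin_start, schedule))
    out <- df |>
      dplyr::filter(!masked) |>
      dplyr::group_by(zt_h) |>
      dplyr::summarise(value = mean(value), n = dplyr::n(), .groups = "drop")
    return(tidyr::complete(out, zt_h = 0:23,
                           fill = list(value = NA_real_, n = 0L)))
  }
  unit <- if (scale == "day") 86400 else 7 * 86400
  df$grp <- as.integer(floor((df$bin_start - t0) / unit)) + 1L
  out <- df |>
    dplyr::group_by(grp) |>
    dplyr::summarise(value = sum(value[!masked]), n_hours = dplyr::n(),
                     n_masked = sum(masked), .groups = "drop")
  names(out)[1] <- scale
  out
}

#' Cohort mean and standard error
#'
#' Collapses a long per-animal table to per-bin cohort mean +/- SEM over the
#' animals contributing an unmasked value to that bin.
#'
#' @param df Long tibble with an `animal` column, a value column, and any
#'   number of key columns identifying the bin (day, `zt_h`, channel, ...).
#' @param value Name of the value column (string); default `"value"`.
#' @param by Character vector of key columns; default: all columns except
#'   `animal` and the value column.
#' @return Tibble with the key columns plus `mean`, `sem`, `n_animals`.
#'   SEM is `NA` for a single animal.
#' @export
aggregate_cohort <- function(df, value = "value", by = NULL) {
  stopifnot("animal" %in% names(df), value %in% names(df))
  if (nrow(df) == 0 || length(unique(df$animal)) == 0) {
    stop("at least one animal is required", call. = FALSE)
  }
  if (is.null(by)) by <- setdiff(names(df), c("animal", value))
  v <- rlang::sym(value)
  df |>
    dplyr::filter(!is.na(!!v)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(!!v),
      sem = stats::sd(!!v) / sqrt(dplyr::n()),
      n_animals = dplyr::n(),
      .groups = "drop"
    )
}
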