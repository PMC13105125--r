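# Ethogram processing: video-scorer CSVs -> time-resolved behavior
# intervals -> grouped labels -> hourly occupancy and daily time budgets.

#' Default behavior grouping
#'
#' Video scorers emit 40+ fine-grained labels ("walk left", "eat zone 2",
#' ...) that are conventionally collapsed into ~15 named behavior groups
#' plus "Other". The shipped map covers the usual vocabulary of home-cage
#' scorers; it is configuration, not code -- labs with a different scorer
#' vocabulary should edit the CSV (columns `raw_label, group_label`) or pass
#' their own tibble. Any label absent from the map falls through to
#' `"Other"`.
#'
#' @param path Optional path to a custom grouping CSV; default: the map
#'   shipped with the package.
#' @return Tibble with columns `raw_label`, `group_label`.
#' @export
behavior_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "behavior_groups.csv", package = "homecagr")
  }
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("raw_label", "group_label") %in% names(out)))
  out[, c("raw_label", "group_label")]
}

#' Parse a segment log file
#'
#' Each 4-hour video segment has a small text log recording the video path,
#' the segment's absolute start time (POSIX seconds), and the frame rate.
#'
#' @param path Path to the log file (`key: value` lines).
#' @return List with `video`, `start_posix`, `fps`.
#' @export
parse_segment_log <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  kv <- strsplit(lines[nzchar(lines)], ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), character(1))
  need <- c("video", "start_posix", "fps")
  if (!all(need %in% keys)) {
    stop(sprintf("segment log '%s' missing keys: %s", path,
                 paste(setdiff(need, keys), collapse = ", ")), call. = FALSE)
  }
  list(video = vals[keys == "video"][1],
       start_posix = as.numeric(vals[keys == "start_posix"][1]),
       fps = as.numeric(vals[keys == "fps"][1]))
}

#' Parse a video-scorer ethogram CSV
#'
#' The scorer records behavior in frame units: each row is a behavior label,
#' a 0-based start frame, and a frame count. Absolute time is resolved from
#' the segment's start time and frame rate:
#' `t_start = segment_start + start_frame / fps`,
#' `duration_s = n_frames / fps`.
#'
#' @param path Path to the ethogram CSV (columns `behavior, start_frame,
#'   n_frames`; header auto-detected).
#' @param segment_start Segment start, POSIX seconds.
#' @param fps Frame rate (frames/second); default 30.
#' @param segment_frames Segment length in frames; default 4 h at `fps`.
#'   Intervals extending past the segment are an error.
#' @return Tibble with columns `raw_label`, `start_frame`, `n_frames`,
#'   `t_start`, `duration_s`, sorted by `start_frame`.
#' @export
parse_ethogram <- function(path, segment_start, fps = 30,
                           segment_frames = round(4 * 3600 * fps)) {
  stopifnot(file.exists(path), fps > 0)
  lines <- readr::read_lines(path)
  empty <- tibble::tibble(raw_label = character(), start_frame = integer(),
                          n_frames = integer(), t_start = numeric(),
                          duration_s = numeric())
  if (length(lines) == 0) return(empty)
  f1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  skip <- length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2])))
  body <- if (skip) lines[-1] else lines
  if (length(body) == 0) return(empty)
  fields <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of '%s'", bad[1] + skip, path), call. = FALSE)
  }
  lab <- vapply(fields, `[`, character(1), 1)
  sf <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  nf <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  if (anyNA(sf) || anyNA(nf)) {
    bad <- which(is.na(sf) | is.na(nf))[1]
    stop(sprintf("non-integer frame field at line %d of '%s'", bad + skip, path),
         call. = FALSE)
  }
  if (any(nf < 1)) stop("n_frames must be >= 1", call. = FALSE)
  over <- which(sf + nf > segment_frames)
  if (length(over) > 0) {
    stop(sprintf(
      "interval at line %d of '%s' extends past the segment (%d + %d > %d frames)",
      over[1] + skip, path, sf[over[1]], nf[over[1]], as.integer(segment_frames)),
      call. = FALSE)
  }
  out <- tibble::tibble(raw_label = lab, start_frame = sf, n_frames = nf,
                        t_start = segment_start + sf / fps,
                        duration_s = nf / fps)
  dplyr::arrange(out, start_frame)
}

#' Group fine-grained behavior labels
#'
#' Adds a `group_label` column by looking each `raw_label` up in the
#' grouping map; unmapped labels become `"Other"`. Durations are untouched,
#' so per-group totals equal the sum of their member raw durations, and
#' grouping already-grouped labels is a no-op when group names are mapped
#' to themselves (the default map includes identity rows for every group).
#'
#' @param intervals Tibble from [parse_ethogram()].
#' @param grouping Tibble with columns `raw_label`, `group_label`; default
#'   [behavior_groups()].
#' @return `intervals` with an added/overwritten `group_label` column.
#' @export
group_behaviors <- function(intervals, grouping = behavior_groups()) {
  stopifnot(all(c("raw_label", "group_label") %in% names(grouping)))
  map <- stats::setNames(grouping$group_label, grouping$raw_label)
  g <- unname(map[intervals$raw_label])
  g[is.na(g)] <- "Other"
  intervals$group_label <- g
  intervals
}

#' Keep the top-n behavior groups, lump the rest into "Other"
#'
#' Groups are ranked globally by total duration; everything outside the top
#' `n` is relabelled `"Other"`.
#'
#' @param intervals Grouped intervals (with `group_label`, `duration_s`).
#' @param n Number of groups to keep; default 15.
#' @return `intervals` with `group_label` lumped.
#' @export
lump_behaviors <- function(intervals, n = 15) {
  totals <- intervals |>
    dplyr::filter(group_label != "Other") |>
    dplyr::group_by(group_label) |>
    dplyr::summarise(total = sum(duration_s), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(total))
  keep <- utils::head(totals$group_label, n)
  intervals$group_label[!(intervals$group_label %in% keep)] <- "Other"
  intervals
}

# Split intervals at absolute-hour boundaries, pro-rata. Returns a tibble
# (group_label, hour_bin, seconds) with one row per (interval, hour) piece.
split_at_hours <- function(intervals) {
  t0 <- intervals$t_start
  t1 <- intervals$t_start + intervals$duration_s
  first_bin <- floor(t0 / 3600)
  last_bin <- ceiling(t1 / 3600) - 1
  n_pieces <- pmax(as.integer(last_bin - first_bin) + 1L, 1L)
  row <- rep(seq_len(nrow(intervals)), n_pieces)
  bin <- unlist(lapply(seq_len(nrow(intervals)),
                       function(i) seq(first_bin[i], by = 1, length.out = n_pieces[i])))
  lo <- pmax(bin * 3600, t0[row])
  hi <- pmin((bin + 1) * 3600, t1[row])
  tibble::tibble(group_label = intervals$group_label[row],
                 hour_bin = bin, seconds = hi - lo)
}

#' Mean hourly occupancy per behavior
#'
#' Accumulates seconds spent in each behavior group within each absolute
#' hour (intervals crossing an hour boundary are split pro-rata, so no
#' seconds are created or lost), then divides each ZT hour's total by the
#' number of times that hour occurs in the dataset -- the number of
#' distinct absolute hour bins overlapped by any scored interval. Partially
#' scored hours count as full occurrences.
#'
#' @param intervals Grouped intervals (columns `group_label`, `t_start`,
#'   `duration_s`).
#' @param schedule A [light_schedule()].
#' @return Tibble with columns `group_label`, `zt_h` (0--23),
#'   `mean_seconds` (in `[0, 3600]`), `n_hours` (occurrences of that ZT
#'   hour). Missing (group, hour) combinations are 0.
#' @export
hourly_occupancy <- function(intervals, schedule) {
  stopifnot(all(c("group_label", "t_start", "duration_s") %in% names(intervals)))
  if (nrow(intervals) == 0) {
    return(tibble::tibble(group_label = character(), zt_h = integer(),
                          mean_seconds = numeric(), n_hours = integer()))
  }
  pieces <- split_at_hours(intervals)
  pieces <- pieces[pieces$seconds > 0, ]
  covered <- unique(pieces$hour_bin)
  occ_per_zt <- table(factor(as.integer(zt_hour(covered * 3600, schedule)),
                             levels = 0:23))
  totals <- pieces |>
    dplyr::mutate(zt_h = as.integer(zt_hour(hour_bin * 3600, schedule))) |>
    dplyr::group_by(group_label, zt_h) |>
    dplyr::summarise(seconds = sum(seconds), .groups = "drop")
  grid <- tidyr::expand_grid(group_label = unique(intervals$group_label),
                             zt_h = 0:23)
  grid |>
    dplyr::left_join(totals, by = c("group_label", "zt_h")) |>
    dplyr::mutate(
      seconds = ifelse(is.na(seconds), 0, seconds),
      n_hours = as.integer(occ_per_zt[as.character(zt_h)]),
      mean_seconds = ifelse(n_hours > 0, seconds / n_hours, NA_real_)
    ) |>
    dplyr::select(group_label, zt_h, mean_seconds, n_hours)
}

#' Per-behavior percentage of a day
#'
#' Total seconds per behavior group divided by 86400 s. With complete
#' scoring of one day the percentages (including `"Other"`) sum to 100.
#'
#' @param intervals Grouped intervals spanning one (ZT) day.
#' @return Tibble with columns `group_label`, `seconds`, `pct_of_day`,
#'   sorted by descending percentage. Empty input warns and returns zero
#'   rows.
#' @export
percent_of_day <- function(intervals) {
  if (nrow(intervals) == 0) {
    warning("no scored intervals for this day", call. = FALSE)
    return(tibble::tibble(group_label = character(), seconds = numeric(),
                          pct_of_day = numeric()))
  }
  intervals |>
    dplyr::group_by(group_label) |>
    dplyr::summarise(seconds = sum(duration_s), .groups = "drop") |>
    dplyr::mutate(pct_of_day = 100 * seconds / 86400) |>
    dplyr::arrange(dplyr::desc(pct_of_day))
}
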