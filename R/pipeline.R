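# Session manifest + end-to-end pipeline: raw streams -> tidy exports.

#' Pipeline thresholds
#'
#' @param timeout Dispenser refractory period, seconds.
#' @param max_gap Bout-joining gap, seconds.
#' @param qc_threshold Strict hourly beambreak QC threshold.
#' @param spike_max_m Wheel spike threshold, meters/hour.
#' @param top_n_behaviors Behavior groups kept before lumping into "Other".
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(timeout = 3, max_gap = 2, qc_threshold = 500,
                            spike_max_m = 700, top_n_behaviors = 15) {
  stopifnot(timeout >= 0, max_gap >= 0, qc_threshold > 0, spike_max_m > 0,
            top_n_behaviors >= 1)
  structure(list(timeout = timeout, max_gap = max_gap,
                 qc_threshold = qc_threshold, spike_max_m = spike_max_m,
                 top_n_behaviors = top_n_behaviors),
            class = "pipeline_config")
}

#' Read a session manifest
#'
#' The manifest (YAML) describes one animal's recording: stream file paths
#' (relative to the manifest), light schedule, frame rate, swap schedule and
#' phase ranges. [simulate_session()] writes this format.
#'
#' @param path Path to `manifest.yaml`.
#' @return A list with parsed fields; `schedule` is a [light_schedule()],
#'   `swap` a [swap_schedule()], and all stream paths are absolute.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  abs <- function(p) file.path(base, p)
  m$schedule <- light_schedule(m$lights_on, m$photoperiod_h)
  m$digital_paths <- vapply(m$digital_paths, abs, character(1))
  m$analog_paths <- vapply(m$analog_paths, abs, character(1))
  m$ethogram <- lapply(m$ethogram, function(e) list(csv = abs(e$csv), log = abs(e$log)))
  m$swap <- swap_schedule(
    n_days = m$n_days,
    water_period = m$swap$water_period, food_period = m$swap$food_period,
    water_day1 = c(p1 = m$swap$water_day1$p1, p2 = m$swap$water_day1$p2),
    food_day1 = c(p1 = m$swap$food_day1$p1, p2 = m$swap$food_day1$p2)
  )
  m
}

write_export <- function(df, out_dir, name, written) {
  p <- file.path(out_dir, name)
  readr::write_csv(df, p)
  c(written, name)
}

#' Run the full processing pipeline for one session
#'
#' Reads the streams named in the manifest and writes tidy spreadsheet
#' exports: minute/hour/day counts for every poke and dispense channel,
#' wheel bout tables and minute/hour/day distance series, ethogram hourly
#' occupancy and daily time budgets, circadian mean-vector tables for every
#' stream, the preference ledger with daily position/type differences, a QC
#' report, and a JSON run summary carrying the package version and a config
#' hash. A stream whose files are absent is skipped with a warning; a
#' corrupt file is a hard error naming the file. Reruns on identical inputs
#' and configuration reproduce identical exports.
#'
#' @param manifest_path Path to the session `manifest.yaml`.
#' @param out_dir Output directory for exports (created if needed).
#' @param config A [pipeline_config()].
#' @param seed Optional integer recorded in the run summary (the pipeline
#'   itself is deterministic).
#' @return Invisibly, a list with the export `files`, the `summary`, and
#'   the key in-memory tables.
#' @export
run_pipeline <- function(manifest_path, out_dir, config = pipeline_config(),
                         seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- m$t0
  t_end <- t0 + m$n_days * 86400
  sched <- m$schedule
  cm <- channel_map()
  written <- character()
  tables <- list()
  vectors <- list()
  qc <- list()

  ## ---- operant events ------------------------------------------------------
  dig_ok <- length(m$digital_paths) > 0 && all(file.exists(m$digital_paths))
  if (!dig_ok) {
    warning("digital stream missing; skipping operant event stage", call. = FALSE)
  } else {
    events <- dplyr::bind_rows(lapply(m$digital_paths, read_digital_csv)) |>
      dplyr::arrange(t)
    per_channel <- lapply(seq_len(8), function(ch) rising_edges(events, ch))
    for (width in c(minute = 60, hour = 3600, day = 86400)) {
      scale <- names(which(c(minute = 60, hour = 3600, day = 86400) == width))
      long <- purrr::map_dfr(seq_len(8), function(ch) {
        b <- add_zt(bin_counts(per_channel[[ch]], width, t0, t_end), sched)
        tibble::tibble(animal = m$animal_id, name = cm$name[ch],
                       role = cm$role[ch], medium = cm$medium[ch],
                       position = cm$position[ch],
                       bin_start = b$bin_start, zt_h = b$zt_h,
                       count = b$value, masked = b$masked)
      })
      written <- write_export(long, out_dir, sprintf("events_%s.csv", scale), written)
      tables[[sprintf("events_%s", scale)]] <- long
    }
    # QC on total hourly beambreaks across the four poke channels
    bb_hour <- bin_counts(sort(unlist(per_channel[1:4])), 3600, t0, t_end)
    qc$events <- qc_flag_hours(bb_hour, config$qc_threshold)
    # per-channel ZT profiles and circadian vectors
    for (ch in 1:4) {
      hb <- add_zt(bin_counts(per_channel[[ch]], 3600, t0, t_end), sched)
      prof <- aggregate_series(hb, "zt_profile", sched)
      v <- mean_resultant_vector(
        tibble::tibble(zt_h = prof$zt_h,
                       weight = ifelse(is.na(prof$value), 0, prof$value)))
      vectors[[length(vectors) + 1]] <-
        dplyr::mutate(tidy(v), stream = cm$name[ch], .before = 1)
    }
    # daily counts per dispenser -> preference ledger
    daily <- purrr::map_dfr(1:4, function(ch) {
      b <- bin_counts(per_channel[[ch]], 86400, t0, t_end)
      tibble::tibble(animal = m$animal_id, day = seq_len(nrow(b)),
                     medium = cm$medium[ch], position = cm$position[ch],
                     count = b$value)
    })
    ledger <- build_ledger(daily, m$swap)
    written <- write_export(ledger, out_dir, "preference_ledger.csv", written)
    pos_diff <- group_by_swap_state(position_difference(ledger), m$swap) |>
      dplyr::mutate(contrast = "position2_minus_position1")
    typ_diff <- group_by_swap_state(type_difference(ledger), m$swap) |>
      dplyr::mutate(contrast = "treat_minus_regular")
    diffs <- dplyr::bind_rows(
      dplyr::rename(pos_diff, difference = diff_pos2_minus_pos1),
      dplyr::rename(typ_diff, difference = diff_treat_minus_regular)
    )
    written <- write_export(diffs, out_dir, "preference_differences.csv", written)
    tables$ledger <- ledger
    tables$preference_differences <- diffs
  }

  ## ---- wheel ---------------------------------------------------------------
  ana_ok <- length(m$analog_paths) > 0 && all(file.exists(m$analog_paths))
  if (!ana_ok) {
    warning("analog stream missing; skipping wheel stage", call. = FALSE)
  } else {
    samples <- dplyr::bind_rows(lapply(m$analog_paths, read_analog_csv)) |>
      dplyr::arrange(t)
    disp <- decode_displacement(samples)
    meas <- accumulate_windows(disp, window = 1)
    bouts <- segment_bouts(meas, max_gap = config$max_gap)
    written <- write_export(bouts, out_dir, "wheel_bouts.csv", written)
    tables$bouts <- bouts
    for (width in c(minute = 60, hour = 3600, day = 86400)) {
      scale <- names(which(c(minute = 60, hour = 3600, day = 86400) == width))
      b <- add_zt(bin_sum(meas$t, meas$d, width, t0, t_end), sched)
      out <- tibble::tibble(animal = m$animal_id, bin_start = b$bin_start,
                            zt_h = b$zt_h, distance_m = b$value,
                            masked = b$masked)
      written <- write_export(out, out_dir, sprintf("distance_%s.csv", scale), written)
      tables[[sprintf("distance_%s", scale)]] <- out
      if (width == 3600) {
        qc$wheel <- flag_nonphysiological(b, sched, config$spike_max_m)
        prof <- aggregate_series(b, "zt_profile", sched)
        v <- mean_resultant_vector(
          tibble::tibble(zt_h = prof$zt_h,
                         weight = ifelse(is.na(prof$value), 0, prof$value)))
        vectors[[length(vectors) + 1]] <-
          dplyr::mutate(tidy(v), stream = "wheel_distance", .before = 1)
      }
    }
  }

  ## ---- ethogram ------------------------------------------------------------
  eth_ok <- length(m$ethogram) > 0 &&
    all(vapply(m$ethogram, function(e) file.exists(e$csv) && file.exists(e$log),
               logical(1)))
  if (!eth_ok) {
    warning("ethogram stream missing; skipping video-behavior stage", call. = FALSE)
  } else {
    intervals <- purrr::map_dfr(m$ethogram, function(e) {
      info <- parse_segment_log(e$log)
      parse_ethogram(e$csv, info$start_posix, info$fps)
    })
    intervals <- lump_behaviors(group_behaviors(intervals),
                                n = config$top_n_behaviors)
    occ <- hourly_occupancy(intervals, sched)
    written <- write_export(occ, out_dir, "ethogram_occupancy.csv", written)
    tables$occupancy <- occ
    budgets <- intervals |>
      dplyr::mutate(day = experiment_day(t_start, t0)) |>
      dplyr::group_by(day, group_label) |>
      dplyr::summarise(seconds = sum(duration_s), .groups = "drop") |>
      dplyr::mutate(pct_of_day = 100 * seconds / 86400)
    written <- write_export(budgets, out_dir, "ethogram_daily_pct.csv", written)
    tables$daily_budget <- budgets
    for (g in sort(unique(occ$group_label))) {
      sub <- occ[occ$group_label == g, ]
      w <- ifelse(is.na(sub$mean_seconds), 0, sub$mean_seconds)
      if (sum(w) > 0) {
        v <- mean_resultant_vector(tibble::tibble(zt_h = sub$zt_h, weight = w))
        vectors[[length(vectors) + 1]] <-
          dplyr::mutate(tidy(v), stream = paste0("behavior_", g), .before = 1)
      }
    }
  }

  ## ---- cross-stream exports ------------------------------------------------
  if (length(vectors) > 0) {
    vec_tbl <- dplyr::mutate(dplyr::bind_rows(vectors), animal = m$animal_id,
                             .before = 1)
    written <- write_export(vec_tbl, out_dir, "circadian_vectors.csv", written)
    tables$circadian_vectors <- vec_tbl
  }
  qc_tbl <- dplyr::bind_rows(
    if (!is.null(qc$events) && nrow(qc$events) > 0)
      dplyr::mutate(qc$events, stream = "beambreaks_total") else NULL,
    if (!is.null(qc$wheel) && nrow(qc$wheel) > 0)
      dplyr::mutate(dplyr::rename(qc$wheel, count = value), stream = "wheel_distance")
    else NULL
  )
  if (nrow(qc_tbl) == 0) {
    qc_tbl <- tibble::tibble(bin = integer(), bin_start = numeric(),
                             count = numeric(), reason = character(),
                             stream = character())
  }
  written <- write_export(qc_tbl, out_dir, "qc_report.csv", written)
  tables$qc <- qc_tbl

  summary <- list(
    package_version = as.character(utils::packageVersion("homecagr")),
    animal_id = m$animal_id,
    config_hash = rlang::hash(list(config = unclass(config),
                                   manifest = manifest_path)),
    seed = if (is.null(seed)) NA else seed,
    stages = list(events = dig_ok, wheel = ana_ok, ethogram = eth_ok),
    files = as.list(sort(written))
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(files = sort(c(written, "run_summary.json")),
                 summary = summary, tables = tables))
}
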