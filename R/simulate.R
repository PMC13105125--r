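# Synthetic home-cage session generator. Emits the three raw device streams
# (digital event CSV, analog wheel CSV, per-segment ethogram CSVs + logs)
# plus a manifest and a ground-truth sidecar, so every analysis stage can be
# validated against known parameters without hardware.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic mouse and device layer. Event streams are
#' inhomogeneous Poisson processes with von Mises-shaped (exp-cosine)
#' circadian intensity `r(t) = r0 * exp(kappa * (cos(2*pi*(zt - phase)/24) - 1))
#' * exp(kappa)` -- i.e. peak rate `r0 * exp(kappa)` at `zt = phase`. The
#' defaults emulate a nocturnal mouse: poke phases in the early dark period,
#' running peaking around ZT15.7, roughly 7 km/day of steady-state running,
#' a 3:1 sucrose-to-regular-water poke ratio, and a sleep-dominated light
#' phase occupying a bit over 40% of the day.
#'
#' @param seed Integer; fully determines all emitted files.
#' @param n_days Number of simulated days (>= 1).
#' @param animal_id Animal identifier written to the manifest.
#' @param t0 Session start, POSIX seconds; must be a lights-on instant under
#'   `schedule`.
#' @param schedule A [light_schedule()].
#' @param swap A [swap_schedule()] covering `n_days`; default built from
#'   `n_days` with the standard 3-day water / 7-day food periods.
#' @param streams Which raw streams to emit: subset of
#'   `c("digital", "analog", "ethogram")`.
#' @param poke_base_rate Baseline poke rate per content stream, events/hour.
#' @param poke_phase Named vector of circadian peak phases (ZT hours) for
#'   `water_regular`, `water_sucrose`, `food_regular`, `food_fatty`.
#' @param poke_kappa Circadian concentration of poke rates.
#' @param sucrose_multiplier Rate multiplier for sucrose water; default 3.
#' @param fatty_multiplier Rate multiplier for fatty food; default 1.
#' @param place_bias Rate multiplier applied to whatever content occupies
#'   position 2; default 1 (no place preference).
#' @param timeout Dispenser refractory period, seconds.
#' @param run_phase,run_kappa Circadian peak phase and concentration of
#'   running-bout initiation.
#' @param run_bout_rate Baseline bout initiation rate, bouts/hour.
#' @param bout_duration_meanlog,bout_duration_sdlog Log-normal parameters of
#'   bout duration in seconds.
#' @param run_speed,run_speed_sd Mean and SD of per-bout running speed, m/s.
#' @param wheel A [wheel_calibration()].
#' @param sample_rate Encoder logging rate while the wheel moves, Hz.
#' @param fps Video frame rate.
#' @param poke_hold_s Beam-broken duration of one poke, seconds.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_days = 28, animal_id = "sim01",
                       t0 = 1728018000, schedule = light_schedule("05:00", 12),
                       swap = swap_schedule(n_days),
                       streams = c("digital", "analog", "ethogram"),
                       poke_base_rate = 1.5,
                       poke_phase = c(water_regular = 16.97, water_sucrose = 18.29,
                                      food_regular = 17.64, food_fatty = 17.74),
                       poke_kappa = 2,
                       sucrose_multiplier = 3, fatty_multiplier = 1,
                       place_bias = 1, timeout = 3,
                       run_phase = 15.67, run_kappa = 2, run_bout_rate = 4.2,
                       bout_duration_meanlog = log(60), bout_duration_sdlog = 1,
                       run_speed = 0.4, run_speed_sd = 0.08,
                       wheel = wheel_calibration(), sample_rate = 16, fps = 30,
                       poke_hold_s = 0.2) {
  if (n_days < 1) stop("a session must span at least one day", call. = FALSE)
  stopifnot(poke_base_rate >= 0, poke_kappa >= 0, run_kappa >= 0,
            sucrose_multiplier > 0, fatty_multiplier > 0, place_bias > 0,
            run_bout_rate >= 0, run_speed > 0, timeout >= 0, fps > 0,
            sample_rate > 0,
            all(streams %in% c("digital", "analog", "ethogram")))
  if (abs(posix_to_zt(t0, schedule)) > 1e-9) {
    stop("`t0` must coincide with lights-on (ZT0)", call. = FALSE)
  }
  if (max(swap$day) < n_days) stop("swap schedule does not cover n_days", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# Inhomogeneous Poisson times on [t_start, t_end) with intensity
# r0 * exp(kappa * cos(2*pi*(zt - phase)/24)) events/hour, by thinning.
sim_circadian_poisson <- function(r0, kappa, phase, t_start, t_end, schedule) {
  if (r0 <= 0 || t_end <= t_start) return(numeric())
  rmax <- r0 * exp(kappa) / 3600
  n <- stats::rpois(1, rmax * (t_end - t_start))
  if (n == 0) return(numeric())
  cand <- sort(stats::runif(n, t_start, t_end))
  zt <- posix_to_zt(cand, schedule)
  p <- exp(kappa * (cos(2 * pi * (zt - phase) / 24) - 1))
  cand[stats::runif(n) < p]
}

# Internal default behavior repertoire for the ethogram simulator:
# selection weight, circadian peak phase (NA = unmodulated), concentration,
# and mean bout duration. Weighted by weight * exp(kappa*(cos(...)-1)) at
# the current ZT; durations are log-normal around mean_dur_s.
sim_behavior_table <- function() {
  tibble::tribble(
    ~group,    ~weight, ~phase, ~kappa, ~mean_dur_s,
    "sleep",     0.120,    4.5,    1.2,         360,
    "twitch",    0.030,    5.0,    1.0,          10,
    "eat",       0.080,   17.7,    1.5,          60,
    "drink",     0.060,   18.0,    1.5,          20,
    "groom",     0.100,     NA,    0.0,          90,
    "walk",      0.120,   16.0,    1.0,          30,
    "turn",      0.080,   16.0,    1.0,          10,
    "rear",      0.080,   16.5,    1.0,          15,
    "sniff",     0.060,   16.0,    1.0,          20,
    "dig",       0.040,   16.0,    1.0,          40,
    "forage",    0.030,   17.0,    1.0,          30,
    "jump",      0.020,   16.0,    1.0,           5,
    "stretch",   0.020,    5.5,    0.5,          10,
    "pause",     0.080,    6.0,    0.5,          60,
    "hang",      0.010,   16.0,    1.0,          20,
    "Other",     0.010,     NA,    0.0,          15
  )
}

# Simulate per-content poke times over the whole session. Returns a tibble
# (t, medium, content, position) sorted by t.
sim_pokes <- function(cfg) {
  sched <- tibble::as_tibble(cfg$swap)
  mult <- c(water_regular = 1, water_sucrose = cfg$sucrose_multiplier,
            food_regular = 1, food_fatty = cfg$fatty_multiplier)
  out <- list()
  for (stream in names(cfg$poke_phase)) {
    parts <- strsplit(stream, "_", fixed = TRUE)[[1]]
    medium <- parts[1]; content <- parts[2]
    pos_by_day <- sched$position[sched$medium == medium & sched$content == content]
    names(pos_by_day) <- sched$day[sched$medium == medium & sched$content == content]
    for (d in seq_len(cfg$n_days)) {
      pos <- pos_by_day[[as.character(d)]]
      r0 <- cfg$poke_base_rate * mult[[stream]] * if (pos == 2) cfg$place_bias else 1
      tt <- sim_circadian_poisson(r0, cfg$poke_kappa, cfg$poke_phase[[stream]],
                                  cfg$t0 + (d - 1) * 86400, cfg$t0 + d * 86400,
                                  cfg$schedule)
      if (length(tt) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          t = round(tt, 3), medium = medium, content = content, position = pos)
      }
    }
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), t)
  res[!duplicated(res$t), ]  # device timestamps are unique at ms resolution
}

# Simulate merged running bouts: start times from a circadian Poisson
# process, log-normal durations, per-bout speeds; overlapping or nearly
# adjacent bouts (gap < merge_gap) merge into one.
sim_run_bouts <- function(cfg, merge_gap = 3) {
  starts <- sim_circadian_poisson(cfg$run_bout_rate, cfg$run_kappa, cfg$run_phase,
                                  cfg$t0, cfg$t0 + cfg$n_days * 86400, cfg$schedule)
  if (length(starts) == 0) {
    return(tibble::tibble(t_start = numeric(), duration_s = numeric(),
                          speed_mps = numeric(), distance_m = numeric()))
  }
  dur <- stats::rlnorm(length(starts), cfg$bout_duration_meanlog, cfg$bout_duration_sdlog)
  alias_limit <- cfg$wheel$v_max / 2 * cfg$wheel$meters_per_volt * cfg$sample_rate
  speed <- pmin(pmax(stats::rnorm(length(starts), cfg$run_speed, cfg$run_speed_sd),
                     0.05), 0.95 * alias_limit)
  ends <- starts + dur
  # merge bouts whose gap to the previous merged bout is below merge_gap
  m_start <- starts[1]; m_end <- ends[1]; m_dist <- dur[1] * speed[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - m_end < merge_gap) {
      overlap_end <- max(m_end, ends[i])
      m_dist <- m_dist + speed[i] * (ends[i] - max(starts[i], m_end)) *
        (ends[i] > m_end)
      m_end <- overlap_end
    } else {
      out[[length(out) + 1]] <- c(m_start, m_end, m_dist)
      m_start <- starts[i]; m_end <- ends[i]; m_dist <- dur[i] * speed[i]
    }
  }
  out[[length(out) + 1]] <- c(m_start, m_end, m_dist)
  m <- do.call(rbind, out)
  tibble::tibble(
    t_start = m[, 1], duration_s = m[, 2] - m[, 1],
    speed_mps = pmin(m[, 3] / (m[, 2] - m[, 1]), 0.95 * alias_limit)
  ) |>
    dplyr::mutate(distance_m = speed_mps * duration_s)
}

#' Encode true running bouts as absolute-encoder voltage samples
#'
#' Inverts the wheel decoder: while a bout is in progress the encoder
#' voltage advances by `speed / sample_rate / meters_per_volt` volts per
#' sample on a regular grid, wrapping at `v_max`; between bouts the voltage
#' is constant and -- the log being event-driven -- no samples are emitted.
#' Decoding the result with [decode_displacement()] recovers each bout's
#' distance to within one sample's displacement.
#'
#' @param bouts Tibble with columns `t_start`, `duration_s`, `speed_mps`
#'   (non-overlapping, sorted).
#' @param cal A [wheel_calibration()].
#' @param sample_rate Samples per second while moving; default 16.
#' @param v0 Encoder voltage at session start.
#' @param t_first Time of the initial reference sample; default 1 s before
#'   the first bout.
#' @return Tibble with columns `t`, `v`.
#' @export
encode_wheel_voltage <- function(bouts, cal = wheel_calibration(),
                                 sample_rate = 16, v0 = 2.5, t_first = NULL) {
  stopifnot(inherits(cal, "wheel_calibration"))
  alias_limit <- cal$v_max / 2 * cal$meters_per_volt * sample_rate
  if (nrow(bouts) == 0) {
    t_first <- if (is.null(t_first)) 0 else t_first
    return(tibble::tibble(t = t_first, v = v0))
  }
  stopifnot(all(c("t_start", "duration_s", "speed_mps") %in% names(bouts)))
  if (is.unsorted(bouts$t_start)) stop("bouts must be sorted by t_start", call. = FALSE)
  too_fast <- bouts$speed_mps >= alias_limit
  if (any(too_fast)) {
    stop(sprintf(
      "bout speed %.3f m/s at or above the alias limit %.3f m/s (half a revolution per sample)",
      max(bouts$speed_mps), alias_limit), call. = FALSE)
  }
  if (is.null(t_first)) t_first <- bouts$t_start[1] - 1
  n_steps <- pmax(floor(bouts$duration_s * sample_rate), 1L)
  total <- sum(n_steps)
  t <- numeric(total); dv <- numeric(total)
  pos <- 1L
  for (i in seq_len(nrow(bouts))) {
    k <- n_steps[i]
    idx <- pos:(pos + k - 1L)
    t[idx] <- bouts$t_start[i] + seq_len(k) / sample_rate
    dv[idx] <- bouts$speed_mps[i] / sample_rate / cal$meters_per_volt
    pos <- pos + k
  }
  v <- (v0 + cumsum(dv)) %% cal$v_max
  tibble::tibble(t = c(t_first, t), v = c(v0, v))
}

# Build state-snapshot digital records from per-channel rise/fall times.
# pulses: tibble (t, channel, state) of individual pin transitions.
build_digital_records <- function(pulses) {
  cm <- channel_map()
  if (nrow(pulses) == 0) {
    return(tibble::as_tibble(c(list(t = numeric()),
      stats::setNames(rep(list(logical()), 8), cm$name))))
  }
  pulses <- dplyr::arrange(pulses, t)
  n <- nrow(pulses)
  cols <- lapply(seq_len(8), function(ch) {
    x <- rep(NA, n)
    sel <- pulses$channel == ch
    x[sel] <- pulses$state[sel]
    # last observation carried forward; FALSE before the first transition
    idx <- cumsum(!is.na(x))
    vals <- x[!is.na(x)]
    out <- rep(FALSE, n)
    out[idx > 0] <- vals[idx[idx > 0]]
    out
  })
  rec <- tibble::as_tibble(c(list(t = pulses$t),
                             stats::setNames(cols, cm$name)))
  rec[!duplicated(rec$t, fromLast = TRUE), ]
}

# Turn event times into rise/fall pulse pairs on one channel. The beam (or
# command line) stays active hold_s seconds, clipped so consecutive events
# keep distinct rising edges.
event_pulses <- function(times, channel, hold_s) {
  if (length(times) == 0) {
    return(tibble::tibble(t = numeric(), channel = integer(), state = logical()))
  }
  gap_next <- c(diff(times), Inf)
  fall <- round(times + pmin(hold_s, 0.9 * gap_next), 3)
  tibble::tibble(t = c(times, fall),
                 channel = channel,
                 state = rep(c(TRUE, FALSE), each = length(times)))
}

# Simulate the ethogram as a circadian-modulated semi-Markov chain over the
# behavior repertoire, one 4-h segment at a time, covering every frame.
sim_ethogram_segment <- function(cfg, seg_start, seg_frames, beh, raw_pool) {
  frame <- 0L
  labs <- character(); sfs <- integer(); nfs <- integer()
  while (frame < seg_frames) {
    zt <- posix_to_zt(seg_start + frame / cfg$fps, cfg$schedule)
    mod <- ifelse(is.na(beh$phase), 1,
                  exp(beh$kappa * (cos(2 * pi * (zt - beh$phase) / 24) - 1)))
    w <- beh$weight * mod
    g <- sample(beh$group, 1, prob = w)
    dur_s <- stats::rlnorm(1, log(beh$mean_dur_s[beh$group == g]), 0.6)
    nf <- min(max(1L, as.integer(round(dur_s * cfg$fps))), seg_frames - frame)
    pool <- raw_pool[[g]]
    labs <- c(labs, if (length(pool) > 0) sample(pool, 1) else g)
    sfs <- c(sfs, frame); nfs <- c(nfs, nf)
    frame <- frame + nf
  }
  tibble::tibble(behavior = labs, start_frame = sfs, n_frames = nfs)
}

#' Simulate a full home-cage session and write its raw streams
#'
#' Generates poke/dispense events, running bouts, and an ethogram from the
#' configured statistical model, passes them through the same device rules
#' the hardware applies (dispense refractory timeout, event-driven logging,
#' encoder voltage wrap), and writes the raw stream files, a session
#' manifest (`manifest.yaml`), and a ground-truth sidecar
#' (`ground_truth.json`). Identical configurations (including the seed)
#' produce byte-identical files.
#'
#' Only the streams named in `config$streams` are simulated; with
#' `write_files = FALSE` nothing touches disk and the generated tables are
#' only returned in memory (useful for large parameter-recovery runs).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); may be `NULL` when
#'   `write_files = FALSE`.
#' @param write_files Write the raw stream files, manifest and ground
#'   truth? Default: yes when `dir` is given.
#' @return Invisibly, a list with `dir`, `manifest_path`, `manifest`,
#'   `ground_truth`, and the in-memory `pokes`, `dispenses`, `bouts`,
#'   `ethogram`, `digital`, `analog` tables.
#' @export
simulate_session <- function(config, dir = NULL, write_files = !is.null(dir)) {
  stopifnot(inherits(config, "sim_config"))
  if (write_files) {
    if (is.null(dir)) stop("`dir` is required when writing files", call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  cfg <- config
  cm <- channel_map()

  with_sim_seed(cfg$seed, {
    ## --- digital stream ---------------------------------------------------
    pokes <- tibble::tibble(t = numeric(), medium = character(),
                            content = character(), position = integer())
    if ("digital" %in% cfg$streams) pokes <- sim_pokes(cfg)
    disp_list <- list(tibble::tibble(t = numeric(), medium = character(),
                                     position = integer()))
    pulse_list <- list()
    for (m in if ("digital" %in% cfg$streams) c("water", "food") else character()) for (p in 1:2) {
      bb_ch <- cm$channel[cm$role == "beambreak" & cm$medium == m & cm$position == p]
      dp_ch <- cm$channel[cm$role == "dispense" & cm$medium == m & cm$position == p]
      pt <- pokes$t[pokes$medium == m & pokes$position == p]
      dt <- dispense_controller(pt, cfg$timeout)
      if (length(dt) > 0) {
        disp_list[[length(disp_list) + 1]] <-
          tibble::tibble(t = dt, medium = m, position = p)
      }
      pulse_list[[length(pulse_list) + 1]] <- event_pulses(pt, bb_ch, cfg$poke_hold_s)
      pulse_list[[length(pulse_list) + 1]] <- event_pulses(dt, dp_ch, 0.1)
    }
    dispenses <- dplyr::arrange(dplyr::bind_rows(disp_list), t)
    digital <- build_digital_records(dplyr::bind_rows(pulse_list))

    ## --- analog stream ----------------------------------------------------
    bouts <- tibble::tibble(t_start = numeric(), duration_s = numeric(),
                            speed_mps = numeric(), distance_m = numeric())
    analog <- tibble::tibble(t = numeric(), v = numeric())
    if ("analog" %in% cfg$streams) {
      bouts <- sim_run_bouts(cfg)
      analog <- encode_wheel_voltage(bouts, cfg$wheel, cfg$sample_rate,
                                     v0 = 2.5, t_first = cfg$t0)
    }

    ## --- ethogram ---------------------------------------------------------
    beh <- sim_behavior_table()
    groups_map <- behavior_groups()
    raw_pool <- split(groups_map$raw_label, groups_map$group_label)
    n_segments <- cfg$n_days * 6L
    seg_starts <- cfg$t0 + (seq_len(n_segments) - 1) * 4 * 3600
    seg_frames <- as.integer(round(4 * 3600 * cfg$fps))
    ethogram <- if ("ethogram" %in% cfg$streams) {
      purrr::map(seg_starts, function(s0) {
        sim_ethogram_segment(cfg, s0, seg_frames, beh, raw_pool)
      })
    } else list()

    ## --- write files ------------------------------------------------------
    files <- list()
    if (write_files && "digital" %in% cfg$streams) {
      files$digital <- "digital_events.csv"
      write_digital_csv(digital, file.path(dir, files$digital))
    }
    if (write_files && "analog" %in% cfg$streams) {
      files$analog <- "analog_wheel.csv"
      write_analog_csv(analog, file.path(dir, files$analog))
    }
    seg_files <- list()
    if (write_files && "ethogram" %in% cfg$streams) {
      dir.create(file.path(dir, "ethogram"), showWarnings = FALSE)
      for (i in seq_len(n_segments)) {
        csv <- sprintf("ethogram/seg_%03d.csv", i)
        log <- sprintf("ethogram/seg_%03d.log", i)
        readr::write_lines(c(
          "behavior,start_frame,n_frames",
          sprintf("%s,%d,%d", ethogram[[i]]$behavior, ethogram[[i]]$start_frame,
                  ethogram[[i]]$n_frames)),
          file.path(dir, csv))
        readr::write_lines(c(
          sprintf("video: seg_%03d.mp4", i),
          sprintf("start_posix: %.3f", seg_starts[i]),
          sprintf("fps: %g", cfg$fps)),
          file.path(dir, log))
        seg_files[[i]] <- list(csv = csv, log = log)
      }
    }

    manifest <- if (!write_files) NULL else list(
      animal_id = cfg$animal_id,
      t0 = cfg$t0,
      n_days = cfg$n_days,
      lights_on = sprintf("%02d:%02d", cfg$schedule$lights_on_utc %/% 3600,
                          (cfg$schedule$lights_on_utc %% 3600) %/% 60),
      photoperiod_h = cfg$schedule$photoperiod_h,
      fps = cfg$fps,
      timeout = cfg$timeout,
      digital_paths = if ("digital" %in% cfg$streams) I(list(files$digital)) else list(),
      analog_paths = if ("analog" %in% cfg$streams) I(list(files$analog)) else list(),
      ethogram = seg_files,
      segment_starts = if (length(seg_files) > 0) seg_starts else list(),
      swap = list(water_period = 3, food_period = 7,
                  water_day1 = list(p1 = "sucrose", p2 = "regular"),
                  food_day1 = list(p1 = "fatty", p2 = "regular")),
      phase_ranges = list(acclimation = c(1, min(14, cfg$n_days)),
                          baseline = if (cfg$n_days > 14) c(15, cfg$n_days) else NULL)
    )
    if (write_files) yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))

    eth_truth <- if (length(ethogram) > 0) {
      dplyr::bind_rows(ethogram) |>
        dplyr::mutate(group_label = {
          map <- stats::setNames(groups_map$group_label, groups_map$raw_label)
          g <- unname(map[behavior]); g[is.na(g)] <- "Other"; g
        }) |>
        dplyr::group_by(group_label) |>
        dplyr::summarise(seconds = sum(n_frames) / cfg$fps, .groups = "drop")
    } else tibble::tibble(group_label = character(), seconds = numeric())

    ground_truth <- list(
      seed = cfg$seed, n_days = cfg$n_days,
      poke_phase = as.list(cfg$poke_phase), poke_kappa = cfg$poke_kappa,
      sucrose_multiplier = cfg$sucrose_multiplier,
      fatty_multiplier = cfg$fatty_multiplier,
      place_bias = cfg$place_bias,
      run_phase = cfg$run_phase, run_kappa = cfg$run_kappa,
      n_pokes_by_content = as.list(table(paste(pokes$medium, pokes$content, sep = "_"))),
      n_dispenses = nrow(dispenses),
      n_bouts = nrow(bouts),
      total_distance_m = sum(bouts$distance_m),
      ethogram_seconds = stats::setNames(as.list(eth_truth$seconds),
                                         eth_truth$group_label)
    )
    if (write_files) {
      jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = 10)
    }

    invisible(list(dir = dir,
                   manifest_path = if (write_files) file.path(dir, "manifest.yaml") else NULL,
                   manifest = manifest, ground_truth = ground_truth,
                   pokes = pokes, dispenses = dispenses, bouts = bouts,
                   ethogram = ethogram, digital = digital, analog = analog))
  })
}
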