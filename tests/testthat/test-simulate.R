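# Synthetic session generator: determinism, device rules, round trips.

test_that("identical configurations produce byte-identical files", {
  d1 <- file.path(tempdir(), "sim_det1")
  d2 <- file.path(tempdir(), "sim_det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_session(sim_config(seed = 5, n_days = 1), d1)
  simulate_session(sim_config(seed = 5, n_days = 1), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_equal(h1, h2)
  # a different seed changes the data
  d3 <- file.path(tempdir(), "sim_det3")
  unlink(d3, recursive = TRUE)
  simulate_session(sim_config(seed = 6, n_days = 1), d3)
  expect_false(all(unname(tools::md5sum(file.path(d3, f1))) == h1))
})

test_that("emitted streams survive the parser round trip", {
  d <- file.path(tempdir(), "sim_rt")
  unlink(d, recursive = TRUE)
  s <- simulate_session(sim_config(seed = 8, n_days = 1), d)
  # digital: parsed records equal the in-memory table; per-channel rising
  # edges recover the simulated poke times exactly (ms-quantized at source)
  ev <- read_digital_csv(file.path(d, "digital_events.csv"))
  expect_equal(as.data.frame(ev), as.data.frame(s$digital), tolerance = 1e-9)
  cm <- channel_map()
  for (m in c("water", "food")) for (p in 1:2) {
    ch <- cm$name[cm$role == "beambreak" & cm$medium == m & cm$position == p]
    expect_equal(rising_edges(ev, ch),
                 s$pokes$t[s$pokes$medium == m & s$pokes$position == p])
  }
  # analog: voltages at 1e-6 V, times at 1 ms
  an <- read_analog_csv(file.path(d, "analog_wheel.csv"))
  expect_equal(nrow(an), nrow(s$analog))
  expect_equal(an$v, s$analog$v, tolerance = 1e-6)
  expect_equal(an$t, s$analog$t, tolerance = 1e-3)
  # ethogram: frames round trip exactly and segments cover every frame
  seg1 <- parse_ethogram(file.path(d, "ethogram", "seg_001.csv"),
                         segment_start = 1728018000, fps = 30)
  expect_equal(seg1$n_frames, s$ethogram[[1]]$n_frames)
  expect_equal(sum(seg1$n_frames), 4 * 3600 * 30)
})

test_that("the emitted dispense stream respects the refractory minimum", {
  d <- file.path(tempdir(), "sim_disp")
  unlink(d, recursive = TRUE)
  s <- simulate_session(sim_config(seed = 12, n_days = 2,
                                   streams = "digital",
                                   poke_base_rate = 8), d)
  ev <- read_digital_csv(file.path(d, "digital_events.csv"))
  for (ch in 5:8) {
    dt <- rising_edges(ev, ch)
    if (length(dt) > 1) expect_gte(min(diff(dt)), 3)
  }
  # dispenses are at most as frequent as pokes
  expect_lte(nrow(s$dispenses), nrow(s$pokes))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_days = 0), "at least one day")
  expect_error(sim_config(t0 = 1728018000 + 1234), "lights-on")
})

test_that("wheel voltage encoding inverts the decoder", {
  cal <- wheel_calibration()
  # one bout, 10 m at 0.5 m/s: decoded within one sample displacement
  b <- tibble::tibble(t_start = 100, duration_s = 20, speed_mps = 0.5)
  v <- encode_wheel_voltage(b, cal)
  dec <- decode_displacement(v, cal)
  expect_lt(abs(sum(dec$d) - 10), 0.5 / 16 + 1e-9)
  # zero bouts: constant voltage, zero distance
  v0 <- encode_wheel_voltage(b[0, ], cal)
  expect_equal(sum(decode_displacement(v0, cal)$d), 0)
  # wrap invariance: a bout crossing the 5 V wrap decodes identically to one
  # started far from the wrap
  vw <- encode_wheel_voltage(b, cal, v0 = 4.99)
  vn <- encode_wheel_voltage(b, cal, v0 = 1.00)
  expect_equal(sum(decode_displacement(vw, cal)$d),
               sum(decode_displacement(vn, cal)$d), tolerance = 1e-9)
  # speeds at the aliasing limit are refused with the limit named
  fast <- tibble::tibble(t_start = 0, duration_s = 5, speed_mps = 4)
  expect_error(encode_wheel_voltage(fast, cal), "alias limit")
})

test_that("unmodulated poke rates produce a flat hourly profile", {
  set.seed(1)
  tt <- homecagr:::sim_circadian_poisson(100, 0, 12, T0, T0 + 4 * 86400, SCHED)
  expect_gt(length(tt), 5000)
  counts <- bin_counts(tt, 3600, T0, T0 + 4 * 86400)$value
  hourly <- tapply(counts, rep(0:23, 4), sum)
  expect_gt(stats::chisq.test(hourly)$p.value, 0.01)
})

test_that("simulated phases and preferences are recoverable from the output", {
  # running phase: 14 days, kappa 2, phase ZT16 -> vector within 0.25 h
  s <- simulate_session(sim_config(seed = 3, n_days = 14, streams = "analog",
                                   run_phase = 16),
                        write_files = FALSE)
  m <- accumulate_windows(decode_displacement(s$analog))
  hb <- bin_sum(m$t, m$d, 3600, 1728018000, 1728018000 + 14 * 86400)
  prof <- aggregate_series(hb, "zt_profile", SCHED)
  v <- mean_resultant_vector(
    tibble::tibble(zt_h = prof$zt_h,
                   weight = ifelse(is.na(prof$value), 0, prof$value)),
    hour_offset = 0.5)
  expect_lt(abs(v$direction_zt - 16), 0.25)
  # sucrose multiplier 3 recovered from the emitted event record
  s2 <- simulate_session(sim_config(seed = 4, n_days = 28, streams = "digital"),
                         write_files = FALSE)
  sw <- swap_schedule(28)
  daily <- purrr::map_dfr(1:2, function(p) {
    b <- bin_counts(rising_edges(s2$digital, p), 86400,
                    1728018000, 1728018000 + 28 * 86400)
    tibble::tibble(day = 1:28, medium = "water", position = p, count = b$value)
  })
  led <- build_ledger(daily, sw)
  ratio <- sum(led$count[led$content == "sucrose"]) /
    sum(led$count[led$content == "regular"])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})
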