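# Shared fixtures, built in code.

SCHED <- light_schedule("05:00", 12)
T0 <- 1728018000  # a lights-on instant (05:00 UTC)

# Write a digital event CSV from per-row states; returns the path.
write_digital_fixture <- function(t, states, path = tempfile(fileext = ".csv"),
                                  header = TRUE) {
  stopifnot(nrow(states) == length(t), ncol(states) == 8)
  lines <- paste(sprintf("%.3f", t), apply(states, 1, paste, collapse = ","),
                 sep = ",")
  if (header) lines <- c(paste(c("t", channel_map()$name), collapse = ","), lines)
  writeLines(lines, path)
  path
}

# Random digital fixture toggling a single channel; returns list(path, states).
random_toggle_fixture <- function(n, channel = 1) {
  t <- cumsum(runif(n, 0.01, 1))
  st <- matrix(0L, n, 8)
  st[, channel] <- sample(0:1, n, replace = TRUE)
  list(path = write_digital_fixture(t, st), t = t, states = st[, channel])
}

# Independent brute-force oracles -------------------------------------------

# Edge count by explicit linear scan over a 0/1 state vector.
oracle_edge_count <- function(states) {
  prev <- 0L
  edges <- 0L
  for (s in states) {
    if (s == 1L && prev == 0L) edges <- edges + 1L
    prev <- s
  }
  edges
}

# Histogram by per-event loop.
oracle_bin_counts <- function(times, width, start, end) {
  n <- round((end - start) / width)
  counts <- integer(n)
  for (x in times) {
    i <- floor((x - start) / width) + 1
    if (i >= 1 && i <= n) counts[i] <- counts[i] + 1L
  }
  counts
}

# O(n^2)-style bout grouping: for each measurement decide if it starts a new
# bout by looking at its predecessor only (independent re-derivation).
oracle_segment <- function(t, d, max_gap) {
  starts <- c(1, which(diff(t) > max_gap) + 1)
  ends <- c(starts[-1] - 1, length(t))
  data.frame(t_start = t[starts], t_end = t[ends],
             distance_m = vapply(seq_along(starts),
                                 function(i) sum(d[starts[i]:ends[i]]), numeric(1)))
}

# Per-second ethogram occupancy: rasterize each interval to whole seconds.
oracle_occupancy_seconds <- function(t_start, duration, hour_bin) {
  # total seconds of the interval set inside one absolute hour bin
  lo <- hour_bin * 3600; hi <- lo + 3600
  sum(pmax(0, pmin(t_start + duration, hi) - pmax(t_start, lo)))
}

# Circular mean via complex arithmetic (independent of the trig-sum path).
oracle_circular_mean <- function(w, hour_offset = 0) {
  z <- sum(w * exp(2i * pi * ((0:23) + hour_offset) / 24))
  list(direction = (Arg(z) * 24 / (2 * pi)) %% 24, magnitude = Mod(z) / sum(w))
}
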