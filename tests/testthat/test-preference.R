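# Swap-schedule relabeling, daily differences, and the content-vs-place
# sign diagnostic.

test_that("swap schedule alternates contents on the configured periods", {
  s <- swap_schedule(n_days = 14)
  sw <- tibble::as_tibble(s)
  # both contents present every day for each medium
  daily <- dplyr::count(sw, day, medium)
  expect_true(all(daily$n == 2))
  p1w <- sw$content[sw$medium == "water" & sw$position == 1]
  expect_equal(p1w[1:7],
               c("sucrose", "sucrose", "sucrose", "regular", "regular",
                 "regular", "sucrose"))
  p1f <- sw$content[sw$medium == "food" & sw$position == 1]
  expect_equal(unique(p1f[1:7]), "fatty")
  expect_equal(unique(p1f[8:14]), "regular")
})

test_that("ledger relabels counts by content and conserves totals", {
  sched <- swap_schedule(n_days = 6)
  counts <- tibble::tibble(day = 1, medium = "water", position = c(1L, 2L),
                           count = c(30, 10))
  led <- build_ledger(counts, sched)
  expect_equal(led$count[led$content == "sucrose"], 30)
  expect_equal(led$count[led$content == "regular"], 10)
  # after the day-4 swap the same position counts flip content labels
  counts4 <- dplyr::mutate(counts, day = 4)
  led4 <- build_ledger(counts4, sched)
  expect_equal(led4$count[led4$content == "sucrose"], 10)
  expect_equal(led4$count[led4$content == "regular"], 30)
  # missing day errors
  expect_error(build_ledger(dplyr::mutate(counts, day = 99), sched),
               "missing from the swap schedule")
  # random schedule + counts: content and position marginals partition the
  # same totals
  set.seed(59)
  full <- tidyr::expand_grid(day = 1:28, medium = c("water", "food"),
                             position = c(1L, 2L))
  full$count <- rpois(nrow(full), 50)
  ledr <- build_ledger(full, swap_schedule(28))
  by_pos <- tapply(ledr$count, list(ledr$day, ledr$medium), sum)
  by_con <- tapply(ledr$count, list(ledr$day, ledr$medium), sum)
  expect_equal(by_pos, by_con)
  expect_equal(sum(ledr$count), sum(full$count))
})

test_that("daily differences follow the fixed sign conventions", {
  sched <- swap_schedule(3)
  led <- build_ledger(
    tibble::tibble(day = 1, medium = "water", position = c(1L, 2L),
                   count = c(10, 40)), sched)
  expect_equal(position_difference(led)$diff_pos2_minus_pos1, 30)
  # sucrose is at position 1 on day 1, so treat - regular = 10 - 40
  expect_equal(type_difference(led)$diff_treat_minus_regular, -30)
  # equal counts -> zero
  led0 <- build_ledger(
    tibble::tibble(day = 1, medium = "food", position = c(1L, 2L),
                   count = c(7, 7)), sched)
  expect_equal(position_difference(led0)$diff_pos2_minus_pos1, 0)
  # 28 random days match direct subtraction
  set.seed(61)
  full <- tidyr::expand_grid(day = 1:28, medium = "water", position = c(1L, 2L))
  full$count <- rpois(nrow(full), 100)
  led28 <- build_ledger(full, swap_schedule(28))
  pd <- position_difference(led28)
  oracle <- full$count[full$position == 2] - full$count[full$position == 1]
  expect_equal(pd$diff_pos2_minus_pos1, oracle)
})

# Simulate 28 days of daily counts with a content effect (treat : regular)
# and a place effect (position 2 : position 1), Poisson noise.
sim_daily_counts <- function(sched, medium, content_ratio, place_ratio,
                             base = 100) {
  sw <- tibble::as_tibble(sched)
  sw <- sw[sw$medium == medium, ]
  treat <- c(water = "sucrose", food = "fatty")[[medium]]
  lam <- base * ifelse(sw$content == treat, content_ratio, 1) *
    ifelse(sw$position == 2, place_ratio, 1)
  sw$count <- rpois(nrow(sw), lam)
  sw[, c("day", "medium", "position", "count")]
}

test_that("sign diagnostic separates content from place preference", {
  sched <- swap_schedule(28)
  set.seed(67)
  group_means <- function(diffs, col) {
    tapply(diffs[[col]], diffs$treat_position, mean)
  }
  # pure content preference (3:1): type difference positive in both swap
  # groups, position difference flips sign
  dc <- sim_daily_counts(sched, "water", content_ratio = 3, place_ratio = 1)
  led <- build_ledger(dc, sched)
  td <- group_by_swap_state(type_difference(led), sched)
  pd <- group_by_swap_state(position_difference(led), sched)
  expect_true(all(group_means(td, "diff_treat_minus_regular") > 0))
  expect_equal(sort(sign(group_means(pd, "diff_pos2_minus_pos1"))), c(-1, 1),
               ignore_attr = TRUE)
  # pure place preference: mirrored pattern
  dp <- sim_daily_counts(sched, "food", content_ratio = 1, place_ratio = 3)
  ledp <- build_ledger(dp, sched)
  tdp <- group_by_swap_state(type_difference(ledp), sched)
  pdp <- group_by_swap_state(position_difference(ledp), sched)
  expect_true(all(group_means(pdp, "diff_pos2_minus_pos1") > 0))
  expect_equal(sort(sign(group_means(tdp, "diff_treat_minus_regular"))), c(-1, 1),
               ignore_attr = TRUE)
  # no preference: group means near zero (|mean| << base count)
  d0 <- sim_daily_counts(sched, "water", 1, 1)
  pd0 <- group_by_swap_state(position_difference(build_ledger(d0, sched)), sched)
  expect_true(all(abs(group_means(pd0, "diff_pos2_minus_pos1")) < 20))
})

test_that("sign diagnostic classifies 3:1 effects correctly in >= 95% of runs", {
  sched <- swap_schedule(28)
  classify <- function(counts) {
    led <- build_ledger(counts, sched)
    td <- group_by_swap_state(type_difference(led), sched)
    pd <- group_by_swap_state(position_difference(led), sched)
    tm <- tapply(td$diff_treat_minus_regular, td$treat_position, mean)
    pm <- tapply(pd$diff_pos2_minus_pos1, pd$treat_position, mean)
    if (all(tm > 0) && prod(pm) < 0) "content"
    else if (all(pm > 0) && prod(tm) < 0 || all(pm < 0) && prod(tm) < 0) "place"
    else "ambiguous"
  }
  set.seed(71)
  hits <- 0L
  for (i in 1:100) {
    if (classify(sim_daily_counts(sched, "water", 3, 1)) == "content") hits <- hits + 1L
    if (classify(sim_daily_counts(sched, "food", 1, 3)) == "place") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("post-swap exclusion window drops the renormalization days", {
  sched <- swap_schedule(9, water_period = 3)
  diffs <- tibble::tibble(day = 1:9, medium = "water")
  diffs$diff_pos2_minus_pos1 <- 0
  g <- group_by_swap_state(diffs, sched, exclude_days = 1)
  # days 4 and 7 follow a water swap and are excluded; the first block keeps
  # day 1 (no preceding swap)
  expect_setequal(g$day, c(1, 2, 3, 5, 6, 8, 9))
})

test_that("water volume summaries are labelled estimates", {
  est <- estimate_water_volume(
    tibble::tibble(day = 1, position = 1:2, count = c(250, 278)),
    ml_per_dispense = 0.01)
  expect_equal(est$est_ml, c(2.5, 2.78))
  expect_true(all(est$is_estimate))
})
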