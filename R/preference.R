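# Content vs place preference, disentangled by the periodic position swaps:
# sucrose/regular water swap every 3 days, fatty/regular food every 7.

#' Build a swap schedule
#'
#' Each medium has two dispenser positions whose contents swap periodically
#' from a known day-1 assignment: water every `water_period` days, food
#' every `food_period` days. Day `d` belongs to block
#' `floor((d - 1) / period)`; odd blocks carry the swapped assignment.
#' Swaps take effect at ZT0 of the swap day.
#'
#' @param n_days Number of experiment days covered.
#' @param water_period,food_period Swap periods in days; defaults 3 and 7.
#' @param water_day1 Named character vector `c(p1 = ..., p2 = ...)` giving
#'   day-1 water contents; default sucrose at position 1.
#' @param food_day1 Day-1 food contents; default fatty at position 1.
#' @return Long tibble of class `swap_schedule` with columns `day`,
#'   `medium`, `position`, `content`.
#' @export
swap_schedule <- function(n_days = 28, water_period = 3, food_period = 7,
                          water_day1 = c(p1 = "sucrose", p2 = "regular"),
                          food_day1 = c(p1 = "fatty", p2 = "regular")) {
  stopifnot(n_days >= 1, water_period >= 1, food_period >= 1,
            setequal(water_day1, c("sucrose", "regular")),
            setequal(food_day1, c("fatty", "regular")))
  one_medium <- function(medium, day1, period) {
    swapped <- (floor((seq_len(n_days) - 1) / period) %% 2) == 1
    tibble::tibble(
      day = rep(seq_len(n_days), 2),
      medium = medium,
      position = rep(c(1L, 2L), each = n_days),
      content = c(ifelse(swapped, day1[["p2"]], day1[["p1"]]),
                  ifelse(swapped, day1[["p1"]], day1[["p2"]]))
    )
  }
  out <- dplyr::arrange(
    dplyr::bind_rows(one_medium("water", water_day1, water_period),
                     one_medium("food", food_day1, food_period)),
    day, medium, position
  )
  class(out) <- c("swap_schedule", class(out))
  out
}

#' Label daily position counts with their content
#'
#' Joins daily per-position beambreak sums to the swap schedule so every
#' (day, medium, position) count also carries the content occupying that
#' position that day -- the same events under two labelings. Totals are
#' conserved by construction: content sums and position sums are two
#' partitions of the same counts.
#'
#' @param daily_counts Tibble with columns `day`, `medium`, `position`,
#'   `count` (daily beambreak sums per dispenser; extra columns such as
#'   `animal` are carried through).
#' @param schedule A [swap_schedule()] covering every day present.
#' @return `daily_counts` with an added `content` column (the daily
#'   preference ledger).
#' @export
build_ledger <- function(daily_counts, schedule) {
  stopifnot(all(c("day", "medium", "position", "count") %in% names(daily_counts)))
  missing_days <- setdiff(unique(daily_counts$day), unique(schedule$day))
  if (length(missing_days) > 0) {
    stop(sprintf("day(s) %s missing from the swap schedule",
                 paste(missing_days, collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::left_join(daily_counts,
                          tibble::as_tibble(schedule)[, c("day", "medium", "position", "content")],
                          by = c("day", "medium", "position"))
  if (anyNA(out$content)) stop("unmatched (day, medium, position) in schedule", call. = FALSE)
  out
}

#' Daily position difference
#'
#' Always computed as position 2 minus position 1, per day and medium.
#'
#' @param ledger Tibble from [build_ledger()].
#' @return Tibble with grouping columns (`day`, `medium`, and `animal` if
#'   present) plus `diff_pos2_minus_pos1`.
#' @export
position_difference <- function(ledger) {
  by <- intersect(c("animal", "day", "medium"), names(ledger))
  ledger |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      diff_pos2_minus_pos1 = sum(count[position == 2]) - sum(count[position == 1]),
      .groups = "drop"
    )
}

#' Daily type (content) difference
#'
#' Always computed as treat minus regular: sucrose minus regular for water,
#' fatty minus regular for food.
#'
#' @inheritParams position_difference
#' @return Tibble with grouping columns plus `diff_treat_minus_regular`.
#' @export
type_difference <- function(ledger) {
  by <- intersect(c("animal", "day", "medium"), names(ledger))
  ledger |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      diff_treat_minus_regular = sum(count[content != "regular"]) -
        sum(count[content == "regular"]),
      .groups = "drop"
    )
}

#' Assign daily differences to swap-state groups
#'
#' Each daily difference is placed in one of two groups according to where
#' the treat (sucrose water / fatty food) sat that day: `"treat@pos1"` or
#' `"treat@pos2"`. The diagnostic sign pattern across the two groups then
#' separates the two kinds of preference: a pure content preference keeps
#' the type difference positive in both groups while the position
#' difference flips sign between them; a pure place preference is the
#' mirror image. An optional post-swap exclusion window drops the first
#' `exclude_days` days after each swap boundary (behavior can take days to
#' renormalize after interventions); default 0, i.e. swap-day data count
#' toward the new configuration.
#'
#' @param differences Tibble with `day` and `medium` columns (output of
#'   [position_difference()] or [type_difference()]).
#' @param schedule A [swap_schedule()].
#' @param exclude_days Days to drop after each swap boundary; default 0.
#' @return `differences` with an added `treat_position` factor
#'   (`"treat@pos1"` / `"treat@pos2"`), exclusion-window days removed.
#' @export
group_by_swap_state <- function(differences, schedule, exclude_days = 0) {
  stopifnot(all(c("day", "medium") %in% names(differences)), exclude_days >= 0)
  sched <- tibble::as_tibble(schedule)
  treat_pos <- sched |>
    dplyr::filter(content %in% c("sucrose", "fatty")) |>
    dplyr::transmute(day, medium,
                     treat_position = paste0("treat@pos", position))
  out <- dplyr::inner_join(differences, treat_pos, by = c("day", "medium"))
  if (exclude_days > 0) {
    # day is inside the exclusion window when its offset into the current
    # swap block is < exclude_days (block length = the medium's period)
    periods <- sched |>
      dplyr::group_by(medium) |>
      dplyr::summarise(period = infer_period(content[position == 1][order(day[position == 1])]),
                       .groups = "drop")
    out <- dplyr::left_join(out, periods, by = "medium")
    in_window <- ((out$day - 1) %% out$period) < exclude_days &
      out$day > out$period  # the very first block has no preceding swap
    out <- out[!in_window, setdiff(names(out), "period")]
  }
  out
}

# Infer the swap period from the day-ordered content sequence at position 1.
infer_period <- function(content_seq) {
  changes <- which(content_seq[-1] != content_seq[-length(content_seq)])
  if (length(changes) == 0) return(length(content_seq))
  changes[1]
}

#' Estimated daily water volume
#'
#' The system cannot weigh consumed water; a volume summary is estimated as
#' dispense count times a configured drop volume and is labelled as such.
#'
#' @param dispense_counts Tibble with columns `day`, `position`, `count` of
#'   water dispenses.
#' @param ml_per_dispense Drop volume per dispense, mL.
#' @return Tibble with `day`, `position`, `est_ml` and a column
#'   `is_estimate = TRUE`.
#' @export
estimate_water_volume <- function(dispense_counts, ml_per_dispense = 0.01) {
  stopifnot(ml_per_dispense > 0,
            all(c("day", "position", "count") %in% names(dispense_counts)))
  dplyr::mutate(dispense_counts, est_ml = count * ml_per_dispense,
                is_estimate = TRUE)
}
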