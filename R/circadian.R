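# Circular statistics for circadian phase: the mean resultant vector of an
# hourly weight profile (running distance, poke counts, behavior occupancy).

# Reduce hours to [0, 24), collapsing values a rounding hair below 24 to 0.
norm24 <- function(h) {
  h <- h %% 24
  ifelse(24 - h < 1e-9, 0, h)
}

as_hour_weights <- function(w) {
  if (is.data.frame(w)) {
    cols <- intersect(c("zt_h", "weight"), names(w))
    if (length(cols) == 2) {
      h <- as.integer(w$zt_h) %% 24L
      out <- numeric(24)
      agg <- rowsum(as.numeric(w$weight), group = h)
      out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      return(out)
    }
    stop("data-frame input needs columns `zt_h` and `weight`", call. = FALSE)
  }
  w <- as.numeric(w)
  if (length(w) != 24) stop("hourly weights must have length 24 (ZT 0..23)", call. = FALSE)
  w
}

#' Mean resultant vector of an hourly profile
#'
#' Maps the 24-hour cycle onto the circle (hour h -> angle 2*pi*h/24), sums
#' the weighted cosine (x) and sine (y) contributions over all hours, and
#' returns the mean direction (via the two-argument arctangent, converted
#' back to ZT hours) and the mean resultant length
#' `R = sqrt(x^2 + y^2) / sum(w)`, a unitless concentration in `[0, 1]`:
#' 1 when all weight sits in a single hour bin, 0 for a uniform profile.
#'
#' By default each bin is represented by its start hour `h`; set
#' `hour_offset = 0.5` to use bin centers instead (the two conventions
#' differ by a rigid half-hour rotation of the direction).
#'
#' @param w Either a numeric vector of 24 non-negative weights indexed by ZT
#'   hour 0..23, or a data frame with columns `zt_h`, `weight`.
#' @param hour_offset Added to each hour before the angle mapping; default 0.
#' @return Object of class `circadian_vector`: list with `direction_zt`
#'   (hours in `[0, 24)`, `NA` when the magnitude is below `1e-9` and the
#'   direction is undefined), `magnitude`, `total_weight`, `n_nonzero`.
#' @examples
#' w <- numeric(24); w[7] <- 5 # all weight at ZT6
#' mean_resultant_vector(w)
#' @export
mean_resultant_vector <- function(w, hour_offset = 0) {
  w <- as_hour_weights(w)
  if (any(w < 0)) stop("hourly weights must be non-negative", call. = FALSE)
  total <- sum(w)
  if (total <= 0) stop("undefined direction: all hourly weights are zero", call. = FALSE)
  theta <- 2 * pi * ((0:23) + hour_offset) / 24
  x <- sum(w * cos(theta))
  y <- sum(w * sin(theta))
  mag <- sqrt(x^2 + y^2) / total
  dir <- if (mag < 1e-9) NA_real_ else norm24(atan2(y, x) * 24 / (2 * pi))
  structure(
    list(direction_zt = dir, magnitude = mag, total_weight = total,
         n_nonzero = sum(w > 0)),
    class = "circadian_vector"
  )
}

#' @export
print.circadian_vector <- function(x, ...) {
  dir <- if (is.na(x$direction_zt)) "undefined" else sprintf("ZT%.2f", x$direction_zt)
  cat(sprintf("<circadian_vector> direction %s, magnitude %.3f (total weight %g)\n",
              dir, x$magnitude, x$total_weight))
  invisible(x)
}

#' Tidy a circadian vector
#'
#' @param x A `circadian_vector`.
#' @param ... Unused.
#' @return One-row tibble with `direction_zt` and `magnitude`.
#' @exportS3Method generics::tidy
tidy.circadian_vector <- function(x, ...) {
  tibble::tibble(direction_zt = x$direction_zt, magnitude = x$magnitude)
}

#' Glance at a circadian vector
#'
#' @inheritParams tidy.circadian_vector
#' @return One-row tibble with `direction_zt`, `magnitude`, `total_weight`,
#'   `n_nonzero`.
#' @exportS3Method generics::glance
glance.circadian_vector <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Cohort circular mean and dispersion of per-animal phase directions
#'
#' The cohort direction is the direction of the vector sum of unit vectors
#' at each animal's direction. Dispersion is reported as the circular
#' standard error of the mean: `sqrt(-2 * log(Rbar))` (the circular SD, in
#' radians) converted to hours and divided by `sqrt(n)`. The output labels
#' the dispersion explicitly as a circular SEM.
#'
#' @param directions Numeric vector of per-animal directions (ZT hours); at
#'   least 2.
#' @return Tibble with `direction_zt`, `rbar` (mean resultant length of the
#'   unit vectors), `circ_sd_h`, `circ_sem_h`, `n`.
#' @export
vector_dispersion <- function(directions) {
  directions <- directions[!is.na(directions)]
  n <- length(directions)
  if (n < 2) stop("at least 2 animal directions are required", call. = FALSE)
  theta <- 2 * pi * directions / 24
  x <- mean(cos(theta)); y <- mean(sin(theta))
  rbar <- sqrt(x^2 + y^2)
  dir <- norm24(atan2(y, x) * 24 / (2 * pi))
  sd_h <- if (rbar < 1e-12) Inf else sqrt(-2 * log(min(rbar, 1))) * 24 / (2 * pi)
  tibble::tibble(direction_zt = dir, rbar = rbar, circ_sd_h = sd_h,
                 circ_sem_h = sd_h / sqrt(n), n = n)
}
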