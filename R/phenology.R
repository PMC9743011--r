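# Threshold-based phenology detection on irregularly sampled growth series.
#
# All detectors work on per-interval net increments between consecutive
# sessions inside a season window, compare them against a threshold fraction
# (default 5%) of the sum of the positive increments of that season, and
# report interval midpoints. Thresholds are relative, so every detector is
# invariant to uniform scaling of the series. Ties are broken toward the
# earlier interval. Undefined events are NA, never sentinel numbers.

season_slice <- function(series, season) {
  stopifnot(inherits(series, "growth_series") || is.data.frame(series),
            length(season) == 2L, season[1] < season[2])
  s <- series[series$day >= season[1] & series$day <= season[2], , drop = FALSE]
  if (nrow(s) < 2L) stop("fewer than two sessions in season window", call. = FALSE)
  list(day = s$day, value = s$value,
       inc = diff(s$value), dt = diff(s$day),
       mid = s$day[-nrow(s)] + diff(s$day) / 2)
}

#' Detect growth initiation
#'
#' Growth is initiated in the first imaging interval whose net increment
#' reaches `threshold` (default 5%) of the sum of the positive per-interval
#' increments of the season; the event day is the midpoint of that interval.
#' With `basis = "rate"` the per-day rates are compared against the same
#' fraction of the sum of positive rates instead.
#'
#' @param series A growth series (data frame with `day`, `value`).
#' @param season `c(start, end)` window, days.
#' @param threshold Fraction of the seasonal positive-increment sum.
#' @param basis `"increment"` (default) or `"rate"`.
#' @return Event day (midpoint of the qualifying interval), or `NA` with a
#'   warning if no interval qualifies (e.g. a series that never grows).
#' @export
detect_initiation <- function(series, season, threshold = 0.05,
                              basis = c("increment", "rate")) {
  basis <- match.arg(basis)
  s <- season_slice(series, season)
  x <- if (basis == "increment") s$inc else s$inc / s$dt
  tot <- sum(x[x > 0])
  if (tot <= 0) {
    warning("no positive growth in season; initiation undefined", call. = FALSE)
    return(NA_real_)
  }
  j <- which(x >= threshold * tot)
  if (length(j) == 0L) return(NA_real_)
  s$mid[j[1]]
}

#' Detect growth cessation
#'
#' Growth ceases at the midpoint of the second interval of the first pair of
#' consecutive imaging intervals whose net increments are both below
#' `threshold` of the seasonal positive-increment sum. If no such pair
#' exists (growth continues to the end of the window), the midpoint of the
#' last interval is returned and flagged via attribute
#' `ceased_at_last = TRUE`, the convention for series still growing at the
#' final session.
#'
#' @inheritParams detect_initiation
#' @return Event day, with attribute `ceased_at_last` (logical).
#' @export
detect_cessation <- function(series, season, threshold = 0.05,
                             basis = c("increment", "rate")) {
  basis <- match.arg(basis)
  s <- season_slice(series, season)
  if (length(s$inc) < 2L) stop("need at least three sessions in season", call. = FALSE)
  x <- if (basis == "increment") s$inc else s$inc / s$dt
  tot <- sum(x[x > 0])
  thr <- threshold * max(tot, 0)
  below <- x < thr
  pair <- which(below[-length(below)] & below[-1])
  if (length(pair)) {
    return(structure(s$mid[pair[1] + 1L], ceased_at_last = FALSE))
  }
  structure(s$mid[length(s$mid)], ceased_at_last = TRUE)
}

#' Day of maximum standing value
#'
#' The session day (i.e. the day ending an imaging interval) at which the
#' series attains its maximum inside the season; the earliest such session on
#' ties.
#'
#' @inheritParams detect_initiation
#' @return Session day of the maximum.
#' @export
day_of_max_standing <- function(series, season) {
  s <- season_slice(series, season)
  s$day[which.max(s$value)]
}

#' Day of maximum growth rate
#'
#' The midpoint of the imaging interval with the largest per-day rate inside
#' the season; the earliest interval on ties.
#'
#' @inheritParams detect_initiation
#' @return Interval midpoint of the maximum rate.
#' @export
day_of_max_rate <- function(series, season) {
  s <- season_slice(series, season)
  s$mid[which.max(s$inc / s$dt)]
}

phenology_events <- function(initiation, cessation, max_standing, max_rate,
                             ceased_at_last = FALSE) {
  structure(
    list(initiation = initiation,
         cessation = as.numeric(cessation),
         max_standing = max_standing,
         max_rate = max_rate,
         ceased_at_last = isTRUE(ceased_at_last)),
    class = "phenology_events"
  )
}

#' @export
print.phenology_events <- function(x, ...) {
  cat(sprintf(
    "Phenology: initiation %s, cessation %s%s, max standing %s, max rate %s (days)\n",
    format(x$initiation), format(x$cessation),
    if (x$ceased_at_last) " (at last interval)" else "",
    format(x$max_standing), format(x$max_rate)))
  invisible(x)
}

#' Detect all root growth events in a season
#'
#' Convenience wrapper applying [detect_initiation()], [detect_cessation()],
#' [day_of_max_standing()] and [day_of_max_rate()] to one series.
#'
#' @inheritParams detect_initiation
#' @return A `phenology_events` object.
#' @export
detect_root_events <- function(series, season, threshold = 0.05) {
  init <- suppressWarnings(detect_initiation(series, season, threshold))
  cess <- detect_cessation(series, season, threshold)
  phenology_events(
    initiation = init,
    cessation = cess,
    max_standing = day_of_max_standing(series, season),
    max_rate = day_of_max_rate(series, season),
    ceased_at_last = attr(cess, "ceased_at_last")
  )
}

#' Detect shoot growth events
#'
#' Stem-diameter initiation uses the cumulative rule: the first session at
#' which the cumulative diameter increment reaches `threshold` of the total
#' seasonal increment, reported as the midpoint of the interval ending at
#' that session. Shoot-height (elongation) initiation is budburst, supplied
#' externally via `budburst_day`. For both metrics, the day of maximum rate
#' is the midpoint of the interval with the largest per-day rate, and
#' cessation is the midpoint of the interval ending at the session where the
#' maximum value is attained. Increments are proportional to the start
#' value, so all event days are invariant to rescaling.
#'
#' @param height_series,diameter_series Growth series (data frames with
#'   `day`, `value`).
#' @param season `c(start, end)` window, days.
#' @param budburst_day Observed budburst day passed through as the height
#'   initiation event (`NA` if unknown).
#' @param threshold Fraction of the total seasonal increment.
#' @return List with elements `height` and `diameter`, each a
#'   `phenology_events` object.
#' @export
detect_shoot_events <- function(height_series, diameter_series, season,
                                budburst_day = NA_real_, threshold = 0.05) {
  shoot_one <- function(series, initiation) {
    s <- season_slice(series, season)
    total <- s$value[length(s$value)] - s$value[1]
    if (is.na(initiation)) {
      if (total <= 0) {
        warning("flat series; initiation undefined", call. = FALSE)
        initiation <- NA_real_
      } else {
        cum <- cumsum(s$inc)
        j <- which(cum >= threshold * total)
        initiation <- if (length(j)) s$mid[j[1]] else NA_real_
      }
    }
    kmax <- which.max(s$value)
    cess <- if (kmax >= 2L) s$mid[kmax - 1L] else NA_real_
    phenology_events(
      initiation = initiation,
      cessation = cess,
      max_standing = s$day[kmax],
      max_rate = if (total <= 0) NA_real_ else s$mid[which.max(s$inc / s$dt)],
      ceased_at_last = kmax == length(s$day)
    )
  }
  list(height = shoot_one(height_series, budburst_day),
       diameter = shoot_one(diameter_series, NA_real_))
}

#' Root-shoot growth offset
#'
#' The time difference between the peaks of root and shoot growth rates:
#' root max-rate day minus shoot max-rate day. Positive values mean root
#' growth peaked later than shoot growth.
#'
#' @param root_events,shoot_events `phenology_events` objects (or anything
#'   with a `max_rate` element).
#' @return Offset in days (`NA` if either peak is undefined).
#' @export
growth_offset <- function(root_events, shoot_events) {
  root_events$max_rate - shoot_events$max_rate
}

#' Degree-day sum above a threshold
#'
#' Accumulates daily temperature excess over `threshold` (default 5 degrees
#' C). When separate day and night temperatures are given with the day-phase
#' length in hours, each day's contribution is the duty-cycle-weighted sum of
#' the two phases' excesses.
#'
#' @param t_day Daily (or day-phase) temperatures, degrees C.
#' @param threshold Base temperature, degrees C.
#' @param t_night Optional night-phase temperatures.
#' @param hours_day Day-phase length in hours (ignored without `t_night`).
#' @return Degree-day sum (dd).
#' @export
#' @examples
#' degree_days(rep(10, 99))               # 495 dd
#' degree_days(rep(20, 84), t_night = rep(15, 84), hours_day = 18)
degree_days <- function(t_day, threshold = 5, t_night = NULL, hours_day = 24) {
  if (is.null(t_night)) {
    return(sum(pmax(0, t_day - threshold)))
  }
  stopifnot(length(t_night) == length(t_day), hours_day >= 0, hours_day <= 24)
  sum(pmax(0, t_day - threshold) * hours_day / 24 +
        pmax(0, t_night - threshold) * (24 - hours_day) / 24)
}
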