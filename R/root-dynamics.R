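# Standing-length, growth-rate and mortality statistics per unit image area.
#
# l_area  = total live root length / imaged frame area (m m-2), per session.
# Dl_area = difference in l_area between consecutive sessions / interval days.
# Mortality per interval = length of roots dying in the interval (each taken
# at its length at the last session it was seen live) / frame area.

growth_series <- function(day, value, meta = list()) {
  stopifnot(length(day) == length(value), !is.unsorted(day, strictly = TRUE))
  out <- data.frame(day = day, value = value)
  attr(out, "meta") <- meta
  class(out) <- c("growth_series", "data.frame")
  out
}

filter_obs <- function(set, root_class = NULL, seedling = NULL) {
  obs <- set$observations
  if (!is.null(root_class)) obs <- obs[obs$root_class %in% root_class, ]
  if (!is.null(seedling)) obs <- obs[obs$seedling_id %in% seedling, ]
  obs
}

#' Standing root length per unit image area
#'
#' For each imaging session, the total length of live roots divided by the
#' imaged frame area (l_area, m m-2), optionally restricted to one root
#' class and/or seedling.
#'
#' @param set A [root_observation_set()].
#' @param root_class Optional `"short"` or `"long"` filter.
#' @param seedling Optional seedling id filter.
#' @return A `growth_series` data frame with columns `day`, `value`.
#' @export
standing_length <- function(set, root_class = NULL, seedling = NULL) {
  stopifnot(inherits(set, "root_obs_set"))
  obs <- filter_obs(set, root_class, seedling)
  days <- set$schedule$session_days
  live <- obs[obs$status == "live", ]
  tot <- vapply(days, function(d) sum(live$length_m[live$session_day == d]),
                numeric(1))
  growth_series(days, tot / set$schedule$frame_area,
                meta = list(root_class = root_class, seedling = seedling,
                            unit = "m m-2"))
}

#' Net increment of a growth series from a season start
#'
#' Subtracts the value at the season start session from the value at each
#' later session; decreases (mortality exceeding production) yield negative
#' increments.
#'
#' @param series A `growth_series`.
#' @param season `c(start, end)` window in days; `start` must be a session.
#' @return A `growth_series` restricted to the window, values relative to the
#'   start session.
#' @export
net_increment <- function(series, season) {
  stopifnot(inherits(series, "growth_series"), length(season) == 2L)
  if (!season[1] %in% series$day) {
    stop("season start is not a session day", call. = FALSE)
  }
  keep <- series$day >= season[1] & series$day <= season[2]
  out <- series[keep, ]
  out$value <- out$value - series$value[series$day == season[1]]
  rownames(out) <- NULL
  class(out) <- class(series)
  attr(out, "meta") <- attr(series, "meta")
  out
}

#' Per-interval elongation rate of a growth series
#'
#' The difference in value between consecutive sessions divided by the number
#' of days in the interval; by construction both new appearance and the
#' elongation of existing roots contribute. The rate is attached to the
#' session ending the interval (first session gets `NA`), so the rate column
#' has one fewer defined element than the value column.
#'
#' @param series A `growth_series` with at least two sessions.
#' @return The series with an added `rate` column (value day-1) and a
#'   `midpoint` column (interval midpoints, `NA` for the first session).
#' @export
elongation_rate <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  if (nrow(series) < 2L) stop("need at least two sessions", call. = FALSE)
  dt <- diff(series$day)
  series$rate <- c(NA_real_, diff(series$value) / dt)
  series$midpoint <- c(NA_real_, series$day[-nrow(series)] + dt / 2)
  series
}

#' Root mortality per unit image area
#'
#' For each imaging interval, sums the lengths of roots that died in the
#' interval -- a root's dead length is its length at the last session it was
#' seen live, since the disintegrating root's own measurement is unreliable
#' -- normalized by frame area. Reports the per-interval dead length, its
#' per-day rate, the cumulative dead length accumulated from the season (or
#' schedule) start, and the mortality share: cumulative dead length divided
#' by live standing length plus cumulative dead length.
#'
#' @param set A [root_observation_set()].
#' @param root_class,seedling Optional filters as in [standing_length()].
#' @param season Optional `c(start, end)` window; accumulation restarts at
#'   the first session at or after `start` (the convention used when shares
#'   are reported per growing season). Default: accumulate from the first
#'   session of the schedule.
#' @return A `mortality_series` data frame: `day` (interval end), `days`
#'   (interval length), `dead` (m m-2), `rate` (m m-2 day-1), `cum_dead`,
#'   `live` (l_area at the session), `share`.
#' @export
mortality <- function(set, root_class = NULL, seedling = NULL, season = NULL) {
  stopifnot(inherits(set, "root_obs_set"))
  obs <- filter_obs(set, root_class, seedling)
  days <- set$schedule$session_days
  if (!is.null(season)) {
    days <- days[days >= season[1] & days <= season[2]]
    if (length(days) < 2L) stop("fewer than two sessions in season", call. = FALSE)
  }
  area <- set$schedule$frame_area

  # per root: first session seen dead/disappeared and length at last live session
  per_root <- split(obs, obs$root_id)
  death_day <- vapply(per_root, function(r) {
    ed <- r$session_day[r$status %in% c("dead", "disappeared")]
    if (length(ed)) min(ed) else NA_real_
  }, numeric(1))
  last_len <- vapply(per_root, function(r) {
    lv <- r[r$status == "live", ]
    if (nrow(lv)) lv$length_m[which.max(lv$session_day)] else NA_real_
  }, numeric(1))

  ends <- days[-1]
  dead <- vapply(ends, function(d) {
    i <- which(death_day == d & !is.na(last_len))
    sum(last_len[i])
  }, numeric(1)) / area

  live <- standing_length(set, root_class, seedling)
  live <- live$value[match(ends, live$day)]

  dt <- diff(days)
  cum_dead <- cumsum(dead)
  out <- data.frame(
    day = ends, days = dt, dead = dead, rate = dead / dt,
    cum_dead = cum_dead, live = live,
    share = ifelse(live + cum_dead > 0, cum_dead / (live + cum_dead), 0)
  )
  class(out) <- c("mortality_series", "data.frame")
  out
}

#' Root morphology summary with sector upscaling
#'
#' Summarizes scanned root morphology per diameter class and derives specific
#' root length (SRL, length over dry mass) and tissue density (dry mass over
#' volume). Scanned sector totals are upscaled to the whole container by the
#' volume ratio.
#'
#' @param scan_table Data frame with columns `diameter_class`, `length_m`,
#'   `surface_m2`, `volume_cm3`, `tips`.
#' @param masses Data frame with columns `diameter_class`, `mass_g`, matching
#'   the classes of `scan_table` (classes without a mass get `NA` ratios).
#' @param sector_volume,total_volume Sector and container soil volumes (same
#'   unit); their ratio is the upscaling factor (default 1: sector = whole
#'   container).
#' @return Data frame per diameter class with upscaled `length_m`,
#'   `surface_m2`, `volume_cm3`, `tips`, `mass_g`, and ratios `srl_m_g`,
#'   `tissue_density_kg_m3`, `tips_per_cm`.
#' @export
morphology_summary <- function(scan_table, masses,
                               sector_volume = 1, total_volume = sector_volume) {
  req <- c("diameter_class", "length_m", "surface_m2", "volume_cm3", "tips")
  stopifnot(all(req %in% names(scan_table)),
            all(c("diameter_class", "mass_g") %in% names(masses)),
            sector_volume > 0, total_volume > 0)
  f <- total_volume / sector_volume
  out <- scan_table[req]
  out[c("length_m", "surface_m2", "volume_cm3", "tips")] <-
    out[c("length_m", "surface_m2", "volume_cm3", "tips")] * f
  out$mass_g <- masses$mass_g[match(out$diameter_class, masses$diameter_class)] * f
  zero_mass <- !is.na(out$mass_g) & out$mass_g == 0 & out$length_m > 0
  if (any(zero_mass)) {
    stop("zero mass with nonzero length: SRL undefined for class(es) ",
         paste(out$diameter_class[zero_mass], collapse = ", "), call. = FALSE)
  }
  out$srl_m_g <- out$length_m / out$mass_g
  # g cm-3 -> kg m-3
  out$tissue_density_kg_m3 <- 1000 * out$mass_g / out$volume_cm3
  out$tips_per_cm <- out$tips / (out$length_m * 100)
  out
}

#' Variance-stabilizing helper transforms
#'
#' Pure transforms conventionally applied before mixed-model analysis of
#' these series: natural log (with optional offset for zeros) and the logit
#' for proportions. No model fitting is performed here.
#'
#' @param x Numeric vector.
#' @param offset Added before the log to accommodate zeros.
#' @return Transformed vector.
#' @export
ln_transform <- function(x, offset = 0) log(x + offset)

#' @rdname ln_transform
#' @export
logit_transform <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("proportions must be in [0, 1]",
                                             call. = FALSE)
  stats::qlogis(x)
}
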