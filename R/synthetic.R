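# Synthetic-data generators with known ground truth.
#
# These emulate the observation processes of a two-season soil-temperature
# experiment on tree seedlings: interval imaging of individual roots at ca.
# 3-week intervals, shoot measurements every 5-9 days, 36-frequency
# impedance spectra in four treatment classes, and linear chamber
# concentration drifts. Every generator takes an explicit seed, uses a
# single pseudo-random stream, and returns the latent truth alongside the
# observations so downstream estimators have recovery tests.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Default study imaging schedule
#'
#' Two 105-day growing seasons separated by dormancy, imaged every 21 days;
#' day 0 is the start of the second growing season (GS2), negative days
#' reach back into the first season (GS1) as in the study's reporting
#' convention.
#'
#' @return An [imaging_schedule()] with seasons GS1, D1, GS2, D2.
#' @export
default_schedule <- function() {
  imaging_schedule(
    session_days = seq(-168, 168, by = 21),
    seasons = list(GS1 = c(-168, -63), D1 = c(-63, 0),
                   GS2 = c(0, 105), D2 = c(105, 168))
  )
}

#' Parameters for the root demography generator
#'
#' Defaults encode the study conditions: four soil-temperature treatments
#' (Cool, Warm, ECLW, EWLC) with four seedlings each; short-root longevity
#' Weibull with treatment-dependent medians of roughly 200-235 days; long
#' roots longer-lived without treatment differences; root appearance as a
#' unimodal (truncated Gaussian) bump within each growing season.
#'
#' @param n_seedlings Seedlings per treatment.
#' @param schedule An [imaging_schedule()].
#' @param treatments Named list; per treatment a list with Weibull `shape`
#'   and `scale` (days) for short-root longevity.
#' @param long_longevity Weibull `shape`/`scale` for long roots (shared
#'   across treatments).
#' @param appearance_intensity Function of study day giving the relative
#'   rate of new-root appearance (unimodal bump per growing season).
#' @param expected_roots Named numeric: expected short and long roots per
#'   seedling over the whole study.
#' @param elongation_rate Mean per-root length growth per imaging interval,
#'   m.
#' @param disappearance_lag Imaging sessions between first "dead" record and
#'   disappearance from the image (0: roots vanish without a dead record).
#' @param seed Integer seed.
#' @return List of class `"demography_params"`.
#' @export
demography_params <- function(
    n_seedlings = 4L,
    schedule = default_schedule(),
    treatments = list(
      Cool = list(shape = 2, scale = 235 / sqrt(log(2))),
      Warm = list(shape = 2, scale = 200 / sqrt(log(2))),
      ECLW = list(shape = 2, scale = 204 / sqrt(log(2))),
      EWLC = list(shape = 2, scale = 234 / sqrt(log(2)))
    ),
    long_longevity = list(shape = 2, scale = 238 / gamma(1.5)),
    appearance_intensity = NULL,
    expected_roots = c(short = 50, long = 16),
    elongation_rate = 0.002,
    disappearance_lag = 2L,
    seed = 1L) {
  stopifnot(inherits(schedule, "imaging_schedule"),
            n_seedlings >= 0, elongation_rate > 0, disappearance_lag >= 0)
  for (tr in treatments) {
    if (tr$shape <= 0 || tr$scale <= 0) {
      stop("Weibull shape and scale must be positive", call. = FALSE)
    }
  }
  if (is.null(appearance_intensity)) {
    mids <- vapply(schedule$seasons[c("GS1", "GS2")], mean, numeric(1))
    appearance_intensity <- function(day) {
      stats::dnorm(day, mids[1], 20) + stats::dnorm(day, mids[2], 20)
    }
  }
  structure(
    list(n_seedlings = as.integer(n_seedlings), schedule = schedule,
         treatments = treatments, long_longevity = long_longevity,
         appearance_intensity = appearance_intensity,
         expected_roots = expected_roots,
         elongation_rate = elongation_rate,
         disappearance_lag = as.integer(disappearance_lag),
         seed = as.integer(seed)),
    class = "demography_params"
  )
}

#' Simulate interval-observed root demography
#'
#' Draws roots per seedling with an appearance session sampled from the
#' appearance intensity (evaluated at the session days: a simulated root is
#' first detectable at the session where it appears, so no root escapes
#' observation and recovered longevities are unbiased when ages are measured
#' from the first live session), latent death days from the treatment's
#' (short roots) or the shared (long roots) Weibull longevity distribution,
#' and renders what the imaging schedule would record: absent before
#' appearance, live with accumulating length while alive, dead from the
#' first session after the latent death day, disappeared
#' `disappearance_lag` sessions later. The latent truth (appearance day,
#' death day, longevity) is attached for recovery tests; each observed death
#' interval contains its latent death day, and roots alive at the last
#' session are right-censored.
#'
#' @param params A [demography_params()] object.
#' @return A [root_observation_set()] with `truth` attached.
#' @export
simulate_root_demography <- function(params) {
  stopifnot(inherits(params, "demography_params"))
  sched <- params$schedule
  days <- sched$session_days
  if (length(days) == 0L) stop("schedule has no sessions", call. = FALSE)
  w <- params$appearance_intensity(days)
  w[w < 0] <- 0
  if (sum(w) <= 0) stop("appearance intensity is zero everywhere", call. = FALSE)

  with_seed(params$seed, {
    obs_list <- list()
    truth_list <- list()
    counter <- 0L
    for (tr in names(params$treatments)) {
      for (s in seq_len(params$n_seedlings)) {
        seedling <- sprintf("%s_s%d", tr, s)
        for (cls in c("short", "long")) {
          n <- stats::rpois(1, params$expected_roots[[cls]])
          if (n == 0L) next
          lon_par <- if (cls == "short") params$treatments[[tr]] else params$long_longevity
          appear <- sample(days, n, replace = TRUE, prob = w)
          longevity <- stats::rweibull(n, lon_par$shape, lon_par$scale)
          death <- appear + longevity
          for (r in seq_len(n)) {
            live_idx <- which(days >= appear[r] & days < death[r])
            if (length(live_idx) == 0L) next # zero-longevity degenerate draw
            counter <- counter + 1L
            root_id <- sprintf("r%05d", counter)
            status <- rep("absent", length(days))
            status[live_idx] <- "live"
            dead_idx <- which(days >= death[r])
            if (length(dead_idx)) {
              lag <- params$disappearance_lag
              gone <- dead_idx[dead_idx >= dead_idx[1] + lag]
              status[dead_idx] <- "dead"
              status[gone] <- "disappeared"
            }
            len <- numeric(length(days))
            inc <- stats::rgamma(length(live_idx), shape = 4,
                                 scale = params$elongation_rate / 4)
            len[live_idx] <- cumsum(inc)
            len[status != "live"] <- 0
            obs_list[[counter]] <- data.frame(
              root_id = root_id, seedling_id = seedling, treatment = tr,
              root_class = cls, session_day = days, length_m = len,
              status = status
            )
            truth_list[[counter]] <- data.frame(
              root_id = root_id, seedling_id = seedling, treatment = tr,
              root_class = cls, appearance_day = appear[r],
              death_day = death[r], longevity = longevity[r]
            )
          }
        }
      }
    }
    if (length(obs_list) == 0L) {
      obs <- data.frame(root_id = character(0), seedling_id = character(0),
                        treatment = character(0), root_class = character(0),
                        session_day = numeric(0), length_m = numeric(0),
                        status = character(0))
      truth <- NULL
    } else {
      obs <- do.call(rbind, obs_list)
      truth <- do.call(rbind, truth_list)
    }
    root_observation_set(obs, sched, truth = truth)
  })
}

#' Parameters for the shoot growth generator
#'
#' Logistic cumulative growth sampled on an irregular 5-9-day schedule with
#' additive Gaussian noise.
#'
#' @param asymptote Final cumulative increment (e.g. mm, or a proportion of
#'   the start-of-season value).
#' @param midpoint Inflection day (days after season start).
#' @param steepness Logistic rate, day-1.
#' @param interval_range `c(min, max)` days between measurements.
#' @param season `c(start, end)` window, days.
#' @param noise_sd Measurement noise standard deviation.
#' @return List of class `"shoot_sim_params"`.
#' @export
shoot_sim_params <- function(asymptote = 60, midpoint = 50, steepness = 0.1,
                             interval_range = c(5, 9), season = c(0, 105),
                             noise_sd = 0.5) {
  if (asymptote <= 0) stop("asymptote must be positive", call. = FALSE)
  if (steepness <= 0) stop("steepness must be positive", call. = FALSE)
  structure(list(asymptote = asymptote, midpoint = midpoint,
                 steepness = steepness, interval_range = interval_range,
                 season = season, noise_sd = noise_sd),
            class = "shoot_sim_params")
}

#' Simulate a shoot growth series
#'
#' Samples a logistic growth curve on an irregular schedule whose steps are
#' drawn uniformly from `interval_range`, adding Gaussian noise. The true
#' inflection day is attached as attribute `true_midpoint`; with zero noise
#' the series is exactly logistic at the sampled days and monotone.
#'
#' @param params A [shoot_sim_params()] object.
#' @param seed Integer seed.
#' @return A `growth_series` (columns `day`, `value`) with attribute
#'   `true_midpoint`.
#' @export
simulate_shoot_growth <- function(params, seed = 1L) {
  stopifnot(inherits(params, "shoot_sim_params"))
  with_seed(seed, {
    d <- params$season[1]
    days <- d
    while (TRUE) {
      d <- d + sample(seq(params$interval_range[1], params$interval_range[2]), 1)
      if (d > params$season[2]) break
      days <- c(days, d)
    }
    mu <- params$asymptote /
      (1 + exp(-params$steepness * (days - params$midpoint)))
    val <- mu + stats::rnorm(length(days), sd = params$noise_sd)
    out <- growth_series(days, val, meta = list(kind = "shoot"))
    attr(out, "true_midpoint") <- params$midpoint
    out
  })
}

#' Cole-Cole impedance model
#'
#' Single-dispersion Cole-Cole impedance
#' `Z(f) = R_inf + (R_0 - R_inf) / (1 + (i * 2 * pi * f * tau)^alpha)`.
#' With `alpha = 1` this is the Debye relaxation, whose negative imaginary
#' part peaks where `2 * pi * f * tau = 1`.
#'
#' @param frequency_hz Frequencies, Hz.
#' @param r_inf,r0 High- and low-frequency resistance limits, Ohm
#'   (`r0 > r_inf > 0`).
#' @param tau Relaxation time, s.
#' @param alpha Broadening exponent in (0, 1].
#' @return Complex impedance vector.
#' @export
cole_cole_impedance <- function(frequency_hz, r_inf, r0, tau, alpha = 1) {
  if (!(r0 > r_inf && r_inf > 0)) stop("need r0 > r_inf > 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  iw <- complex(real = 0, imaginary = 2 * pi * frequency_hz * tau)
  r_inf + (r0 - r_inf) / (1 + iw^alpha)
}

#' Parameters for the impedance spectrum generator
#'
#' Four treatment classes with class-specific Cole-Cole parameters, measured
#' at 36 log-spaced frequencies between 90 Hz and 200 kHz. Default class
#' parameters reflect the pattern seen in warmed root systems: lower
#' resistance (both limits) in the Warm class, intermediate in the switched
#' treatments.
#'
#' @param classes Named list; per class `c(r_inf, r0, tau, alpha)` or a list
#'   with those names.
#' @param n_per_class Spectra per class.
#' @param noise_sd Gaussian noise sd, Ohm, added independently to real and
#'   imaginary parts.
#' @param frequencies Measurement frequencies, Hz (exactly 36).
#' @param seed Integer seed.
#' @return List of class `"eis_sim_params"`.
#' @export
eis_sim_params <- function(
    classes = list(
      Cool = list(r_inf = 300, r0 = 1800, tau = 3.2e-5, alpha = 0.80),
      Warm = list(r_inf = 220, r0 = 1300, tau = 2.6e-5, alpha = 0.75),
      ECLW = list(r_inf = 280, r0 = 1650, tau = 3.0e-5, alpha = 0.78),
      EWLC = list(r_inf = 260, r0 = 1550, tau = 2.8e-5, alpha = 0.82)
    ),
    n_per_class = 8L,
    noise_sd = 4,
    frequencies = exp(seq(log(90), log(200e3), length.out = 36)),
    seed = 1L) {
  if (length(frequencies) != 36L) {
    stop("the instrument measures exactly 36 frequencies", call. = FALSE)
  }
  for (cl in classes) {
    cl <- as.list(cl)
    if (!(cl$r0 > cl$r_inf && cl$r_inf > 0)) stop("need r0 > r_inf > 0", call. = FALSE)
    if (cl$alpha <= 0 || cl$alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  }
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 noise_sd = noise_sd, frequencies = frequencies,
                 seed = as.integer(seed)),
            class = "eis_sim_params")
}

#' Simulate labelled impedance spectra
#'
#' Draws `n_per_class` spectra per class from the class's Cole-Cole curve
#' plus independent Gaussian noise on the real and imaginary parts.
#'
#' @param params An [eis_sim_params()] object.
#' @return Data frame with columns `sample_id`, `class`, `frequency_hz`,
#'   `z_re`, `z_im`, `magnitude`, `delta`.
#' @export
simulate_eis <- function(params) {
  stopifnot(inherits(params, "eis_sim_params"))
  with_seed(params$seed, {
    rows <- list()
    for (cl in names(params$classes)) {
      p <- as.list(params$classes[[cl]])
      z <- cole_cole_impedance(params$frequencies, p$r_inf, p$r0, p$tau, p$alpha)
      for (i in seq_len(params$n_per_class)) {
        re <- Re(z) + stats::rnorm(length(z), sd = params$noise_sd)
        im <- Im(z) + stats::rnorm(length(z), sd = params$noise_sd)
        rows[[length(rows) + 1L]] <- eis_spectrum(
          params$frequencies, re, im,
          sample_id = sprintf("%s_%02d", cl, i), tissue = "root", class = cl
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a chamber concentration time series
#'
#' Linear concentration drift plus Gaussian noise, recorded at fixed spacing
#' over the chamber deployment (default 7 min sampled every 10 s). The true
#' slope is attached as attribute `true_slope_ppm_h`; a negative slope gives
#' a negative downstream flux (soil sink).
#'
#' @param slope_ppm_h True accumulation rate, ppm per hour.
#' @param intercept_ppm Concentration at closure, ppm.
#' @param duration_min Deployment length, minutes (> 0).
#' @param by_s Sampling interval, s.
#' @param noise_sd Noise sd, ppm.
#' @param seed Integer seed.
#' @return Data frame with columns `time_s`, `conc_ppm`.
#' @export
simulate_chamber_series <- function(slope_ppm_h, intercept_ppm = 0.1,
                                    duration_min = 7, by_s = 10,
                                    noise_sd = 0.002, seed = 1L) {
  if (duration_min <= 0) stop("duration must be positive", call. = FALSE)
  with_seed(seed, {
    t_s <- seq(0, duration_min * 60, by = by_s)
    conc <- intercept_ppm + slope_ppm_h * t_s / 3600 +
      stats::rnorm(length(t_s), sd = noise_sd)
    out <- data.frame(time_s = t_s, conc_ppm = conc)
    attr(out, "true_slope_ppm_h") <- slope_ppm_h
    out
  })
}
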