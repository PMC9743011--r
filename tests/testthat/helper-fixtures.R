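# Shared fixture builders. All fixtures are generated in code; no data files.

# Interval-censor exact lifetimes on a regular imaging grid of `width` days;
# lifetimes beyond `horizon` are right-censored at the last session.
ic_from_times <- function(tt, width = 21, horizon = Inf) {
  L <- floor(tt / width) * width
  R <- L + width
  cens <- R > horizon
  R[cens] <- Inf
  L[cens] <- pmin(L[cens], horizon)
  ic_intervals(L, R)
}

# Small hand-built observation set: three roots on a 4-session schedule.
#   r1: appears by s2, lives to the end           (right-censored)
#   r2: appears by s2, dead at s3, disappeared s4 (death in (21, 42])
#   r3: long root, live from s1, dead at s4       (death in (42, 63])
tiny_root_set <- function() {
  sched <- imaging_schedule(c(0, 21, 42, 63), seasons = list(GS = c(0, 63)))
  obs <- rbind(
    data.frame(root_id = "r1", seedling_id = "s1", treatment = "Cool",
               root_class = "short", session_day = c(0, 21, 42, 63),
               length_m = c(0, 0.010, 0.015, 0.018),
               status = c("absent", "live", "live", "live")),
    data.frame(root_id = "r2", seedling_id = "s1", treatment = "Cool",
               root_class = "short", session_day = c(0, 21, 42, 63),
               length_m = c(0, 0.020, 0, 0),
               status = c("absent", "live", "dead", "disappeared")),
    data.frame(root_id = "r3", seedling_id = "s1", treatment = "Warm",
               root_class = "long", session_day = c(0, 21, 42, 63),
               length_m = c(0.005, 0.012, 0.014, 0),
               status = c("live", "live", "live", "dead"))
  )
  root_observation_set(obs, sched)
}

# Growth series whose per-session values produce the given increments.
series_from_increments <- function(days, increments, start = 0) {
  stopifnot(length(increments) == length(days) - 1L)
  data.frame(day = days, value = start + cumsum(c(0, increments)))
}

# Logistic curve sampled on a grid (noise-free).
logistic_series <- function(days, asymptote = 10, midpoint = 50, steepness = 0.1) {
  data.frame(day = days,
             value = asymptote / (1 + exp(-steepness * (days - midpoint))))
}
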