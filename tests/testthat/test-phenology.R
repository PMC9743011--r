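# Threshold-based phenology detectors, offsets, degree-days.

test_that("initiation follows the 5%-of-positive-increments rule", {
  # increments 0.2 / 5.0 / 10.0 on intervals ending at 20/40/60 plus a flat
  # opening value: positive sum 15.2, 5% threshold 0.76; the first interval
  # reaching it is (20, 40] -> day 30
  s <- series_from_increments(c(0, 20, 40, 60), c(0.2, 5.0, 10.0))
  expect_equal(detect_initiation(s, c(0, 60)), 30)

  # a single positive increment in the first interval
  s2 <- series_from_increments(c(0, 20, 40), c(1, 0))
  expect_equal(detect_initiation(s2, c(0, 40)), 10)

  # an all-zero series has no initiation
  s3 <- series_from_increments(c(0, 20, 40), c(0, 0))
  expect_warning(r <- detect_initiation(s3, c(0, 40)), "undefined")
  expect_true(is.na(r))
})

test_that("cessation needs two consecutive sub-threshold intervals", {
  # increments 5/4/0.1/0.05/0.02; positive sum 9.17, 5% = 0.4585;
  # first qualifying pair is intervals 3 & 4 -> midpoint of interval 4
  s <- series_from_increments(seq(0, 100, by = 20), c(5, 4, 0.1, 0.05, 0.02))
  ces <- detect_cessation(s, c(0, 100))
  expect_equal(as.numeric(ces), 70)
  expect_false(attr(ces, "ceased_at_last"))

  # monotone large growth throughout: flagged fallback at the last interval
  s2 <- series_from_increments(seq(0, 80, by = 20), c(5, 6, 7, 8))
  ces2 <- detect_cessation(s2, c(0, 80))
  expect_equal(as.numeric(ces2), 70)
  expect_true(attr(ces2, "ceased_at_last"))

  # below threshold from the start: midpoint of the second interval
  s3 <- series_from_increments(seq(0, 80, by = 20), c(0.01, 0.01, 5, 5))
  expect_equal(as.numeric(detect_cessation(s3, c(0, 80))), 30)
})

test_that("maxima use first-attained tie-breaks and interval midpoints", {
  s <- data.frame(day = c(0, 20, 40, 60), value = c(0, 2, 12, 12))
  expect_equal(day_of_max_standing(s, c(0, 60)), 40) # earliest on the plateau
  inc <- data.frame(day = c(0, 20, 40, 60), value = cumsum(c(0, 2, 10, 4)))
  expect_equal(day_of_max_rate(inc, c(0, 60)), 30) # rates 0.1/0.5/0.2
  const <- series_from_increments(c(0, 20, 40), c(3, 3))
  expect_equal(day_of_max_rate(const, c(0, 40)), 10) # tie -> first interval
  incr <- data.frame(day = c(0, 20, 40), value = c(0, 1, 5))
  expect_equal(day_of_max_standing(incr, c(0, 40)), 40)
})

test_that("shoot events follow the cumulative rule and budburst pass-through", {
  # cumulative increments 0 / 0.02 / 0.3 / 1.0 of total 1.0: 5% first
  # reached at the session ending interval 2 -> its midpoint
  s <- data.frame(day = c(0, 10, 20, 30), value = c(0, 0.02, 0.3, 1.0))
  ev <- detect_shoot_events(s, s, c(0, 30), budburst_day = 3)
  expect_equal(ev$diameter$initiation, 15)
  expect_equal(ev$height$initiation, 3)
  # cessation: maximum attained at session k -> midpoint of (k-1, k]
  expect_equal(ev$diameter$cessation, 25)
  # proportional rescaling leaves all event days unchanged
  s10 <- transform(s, value = value * 10)
  ev10 <- detect_shoot_events(s10, s10, c(0, 30), budburst_day = 3)
  expect_equal(ev10$diameter$initiation, ev$diameter$initiation)
  expect_equal(ev10$diameter$max_rate, ev$diameter$max_rate)
  # totally flat series: undefined events with a warning
  flat <- data.frame(day = c(0, 10, 20), value = c(1, 1, 1))
  w <- capture_warnings(evf <- detect_shoot_events(flat, flat, c(0, 20)))
  expect_match(w, "undefined", all = TRUE) # one per flat metric
  expect_true(is.na(evf$diameter$initiation))
  expect_true(is.na(evf$height$initiation))
})

test_that("detectors are invariant to uniform scaling of the series", {
  set.seed(6)
  for (rep in 1:5) {
    inc <- rgamma(6, 2, 1) * c(0.1, 1, 3, 2, 0.1, 0.01)
    s <- series_from_increments(seq(0, 126, by = 21), inc)
    sK <- transform(s, value = value * 1000)
    expect_equal(detect_initiation(sK, c(0, 126)), detect_initiation(s, c(0, 126)))
    expect_equal(as.numeric(detect_cessation(sK, c(0, 126))),
                 as.numeric(detect_cessation(s, c(0, 126))))
    expect_equal(day_of_max_rate(sK, c(0, 126)), day_of_max_rate(s, c(0, 126)))
  }
})

test_that("on noiseless logistic growth the event order and peak are right", {
  days <- seq(0, 105, by = 21)
  s <- logistic_series(days, asymptote = 8, midpoint = 50, steepness = 0.12)
  season <- c(0, 105)
  init <- detect_initiation(s, season)
  ces <- as.numeric(detect_cessation(s, season))
  peak <- day_of_max_rate(s, season)
  expect_true(init < peak)
  expect_true(peak <= ces)
  # the max-rate interval contains the true inflection day
  k <- which.max(diff(s$value) / diff(s$day))
  expect_true(days[k] <= 50 && 50 <= days[k + 1])
  # event days stay inside the season window
  expect_true(all(c(init, ces, peak) >= season[1] &
                    c(init, ces, peak) <= season[2]))
})

test_that("offset is the root-minus-shoot peak difference", {
  root <- list(max_rate = 64)
  shoot <- list(max_rate = 50)
  expect_equal(growth_offset(root, shoot), 14)
  expect_equal(growth_offset(shoot, root), -14) # antisymmetry
  expect_equal(growth_offset(root, root), 0)
})

test_that("degree-day sums accumulate excess over the threshold", {
  expect_equal(degree_days(rep(10, 99)), 495)
  expect_equal(degree_days(rep(4, 30)), 0)
  expect_equal(degree_days(rep(5, 10)), 0) # at the threshold, no excess
  # 20 C for 18 h and 15 C for 6 h daily, 84 days
  expect_equal(degree_days(rep(20, 84), t_night = rep(15, 84), hours_day = 18),
               1155)
})
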