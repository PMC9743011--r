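# Standing length, elongation rates, mortality and morphology ratios.

test_that("standing length divides live length by the frame area", {
  set <- tiny_root_set()
  # at session 21: r1 0.010 + r2 0.020 live (short); frame area 0.010764 m2
  sl <- standing_length(set, root_class = "short")
  expect_equal(sl$value[sl$day == 21], 0.030 / 0.010764, tolerance = 1e-6)
  # at session 42 only r1 remains live among short roots
  expect_equal(sl$value[sl$day == 42], 0.015 / 0.010764, tolerance = 1e-6)
  # no live roots of a class -> zero at every session
  none <- standing_length(set, root_class = "short", seedling = "nobody")
  expect_equal(none$value, rep(0, 4))
})

test_that("retroactive reclassification conserves the class-summed l_area", {
  set <- tiny_root_set()
  tot_before <- standing_length(set)$value
  obs <- set$observations
  obs$root_class[obs$root_id == "r2"] <- "long"
  set2 <- root_observation_set(obs, set$schedule)
  short2 <- standing_length(set2, root_class = "short")$value
  long2 <- standing_length(set2, root_class = "long")$value
  expect_equal(short2 + long2, tot_before, tolerance = 1e-12)
})

test_that("net increment is zero at season start and subtracts the baseline", {
  s <- structure(data.frame(day = c(0, 21, 42), value = c(2, 5, 4)),
                 class = c("growth_series", "data.frame"))
  ni <- net_increment(s, c(0, 42))
  expect_equal(ni$value, c(0, 3, 2))
  flat <- s
  flat$value <- rep(7, 3)
  expect_equal(net_increment(flat, c(0, 42))$value, rep(0, 3))
  expect_error(net_increment(s, c(1, 42)), "session day")
})

test_that("elongation rates telescope back to the total change", {
  s <- structure(data.frame(day = c(0, 10, 31, 52), value = c(1, 3, 2.5, 6)),
                 class = c("growth_series", "data.frame"))
  er <- elongation_rate(s)
  expect_equal(er$rate[2], 0.2) # (3-1)/10
  expect_true(er$rate[3] < 0)   # declining series
  expect_equal(sum(er$rate[-1] * diff(er$day)), 6 - 1, tolerance = 1e-12)
})

test_that("mortality uses the last-live length and the share is bounded", {
  set <- tiny_root_set()
  mort <- mortality(set, root_class = "short")
  # r2 died in (21, 42] with last-live length 0.020
  expect_equal(mort$dead[mort$day == 42], 0.020 / 0.010764, tolerance = 1e-6)
  expect_equal(mort$rate[mort$day == 42], 0.020 / 0.010764 / 21, tolerance = 1e-6)
  expect_true(all(mort$share >= 0 & mort$share <= 1))
  # share = cum dead / (live + cum dead): at day 42, live 0.015, dead 0.020
  expect_equal(mort$share[mort$day == 42], 0.020 / 0.035, tolerance = 1e-6)
  # no deaths -> share 0 everywhere
  m_none <- mortality(set, root_class = "short", seedling = "nobody")
  expect_equal(m_none$share, rep(0, 3))
})

test_that("length is conserved: change in l_area = production - mortality", {
  rs <- simulate_root_demography(demography_params(n_seedlings = 2L, seed = 17))
  area <- rs$schedule$frame_area
  obs <- rs$observations
  days <- rs$schedule$session_days
  sl <- standing_length(rs)
  mort <- mortality(rs)
  # production oracle: per interval, sum of per-root live-length increases
  wide <- matrix(0, length(unique(obs$root_id)), length(days),
                 dimnames = list(unique(obs$root_id), days))
  live <- obs[obs$status == "live", ]
  wide[cbind(live$root_id, as.character(live$session_day))] <- live$length_m
  prod <- colSums(pmax(wide[, -1, drop = FALSE] -
                         wide[, -ncol(wide), drop = FALSE], 0)) / area
  expect_equal(diff(sl$value), unname(prod) - mort$dead, tolerance = 1e-9)
})

test_that("mortality share is monotone while standing length declines", {
  rs <- simulate_root_demography(demography_params(n_seedlings = 2L, seed = 23))
  mort <- mortality(rs)
  declining <- diff(mort$live) <= 0
  share_change <- diff(mort$share)
  expect_true(all(share_change[declining] >= -1e-12))
})

test_that("morphology ratios and upscaling follow their definitions", {
  scan <- data.frame(diameter_class = c("<=0.5", "0.5-1"),
                     length_m = c(35.5, 10), surface_m2 = c(0.4, 0.2),
                     volume_cm3 = c(100, 60), tips = c(5000, 800))
  masses <- data.frame(diameter_class = c("<=0.5", "0.5-1"),
                       mass_g = c(1.0, 9.5))
  ms <- morphology_summary(scan, masses)
  expect_equal(ms$srl_m_g[1], 35.5)
  expect_equal(ms$tissue_density_kg_m3[2], 1000 * 9.5 / 60)
  # density example: 9.5 g in 100 cm3 -> 95 kg m-3
  masses2 <- data.frame(diameter_class = "<=0.5", mass_g = 9.5)
  ms2 <- morphology_summary(scan[1, ], masses2)
  expect_equal(ms2$tissue_density_kg_m3, 95)
  # upscaling by the volume ratio; factor 1 is the identity
  up <- morphology_summary(scan, masses, sector_volume = 1, total_volume = 2)
  expect_equal(up$length_m, 2 * ms$length_m)
  expect_equal(up$srl_m_g, ms$srl_m_g) # ratios unchanged by upscaling
  expect_error(
    morphology_summary(scan[1, ],
                       data.frame(diameter_class = "<=0.5", mass_g = 0)),
    "SRL undefined")
})

test_that("statistics are invariant to root id permutation", {
  rs <- simulate_root_demography(
    demography_params(n_seedlings = 1L, expected_roots = c(short = 12, long = 4),
                      seed = 3))
  obs <- rs$observations
  ids <- unique(obs$root_id)
  set.seed(4)
  remap <- stats::setNames(sample(ids), ids)
  obs2 <- obs
  obs2$root_id <- remap[obs$root_id]
  rs2 <- root_observation_set(obs2, rs$schedule)
  expect_equal(standing_length(rs2)$value, standing_length(rs)$value)
  expect_equal(mortality(rs2)$dead, mortality(rs)$dead)
})
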