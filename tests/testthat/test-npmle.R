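# Turnbull NPMLE: oracle equivalences and survival-curve summaries.

# Brute-force EM oracle: identical self-consistency algebra written
# independently (dense loops, no shared code path), run to a much tighter
# tolerance. Innermost intervals are supplied by hand for the toy sets.
brute_force_em <- function(A, tol = 1e-12, max_iter = 1e5) {
  n <- nrow(A)
  m <- ncol(A)
  s <- rep(1 / m, m)
  for (it in seq_len(max_iter)) {
    s_new <- numeric(m)
    for (i in seq_len(n)) {
      denom <- 0
      for (j in seq_len(m)) denom <- denom + A[i, j] * s[j]
      for (j in seq_len(m)) s_new[j] <- s_new[j] + A[i, j] * s[j] / denom
    }
    s_new <- s_new / n
    if (max(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
  }
  s
}

test_that("exact event times reduce the NPMLE to the empirical survivor function", {
  fit <- turnbull_npmle(ic_intervals(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(fit$intervals$mass, rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(survival_at(fit, c(0, 1, 1.5, 2, 2.9, 3, 4)),
               c(1, 2 / 3, 2 / 3, 1 / 3, 1 / 3, 0, 0), tolerance = 1e-8)

  set.seed(101)
  tt <- round(rexp(40, 1 / 50), 1)
  fit <- turnbull_npmle(ic_intervals(tt, tt), tol = 1e-11)
  ecdf_surv <- 1 - stats::ecdf(tt)(sort(unique(tt)))
  expect_equal(survival_at(fit, sort(unique(tt))), ecdf_surv, tolerance = 1e-8)
})

test_that("right-censored-only data reproduce the Kaplan-Meier estimate", {
  skip_if_not_installed("survival")
  set.seed(7)
  tt <- rexp(80, 1 / 10)
  cens <- rexp(80, 1 / 15)
  obs <- pmin(tt, cens)
  ev <- tt <= cens
  fit <- turnbull_npmle(ic_intervals(obs, ifelse(ev, obs, Inf)), tol = 1e-11)
  km <- survival::survfit(survival::Surv(obs, ev) ~ 1)
  expect_equal(survival_at(fit, km$time), km$surv, tolerance = 1e-8)
})

test_that("overlapping toy intervals match the brute-force EM oracle", {
  d <- ic_intervals(c(0, 1, 2), c(2, 3, 4))
  fit <- turnbull_npmle(d, tol = 1e-10)
  # innermost intervals of {(0,2], (1,3], (2,4]} are (1,2] and (2,3]
  expect_equal(fit$intervals$left, c(1, 2))
  expect_equal(fit$intervals$right, c(2, 3))
  A <- rbind(c(1, 0), c(1, 1), c(0, 1)) # containment by hand
  expect_equal(fit$intervals$mass, brute_force_em(A), tolerance = 1e-6)

  # a second, asymmetric toy set
  d2 <- ic_intervals(c(0, 0, 1, 3), c(2, 5, 4, 6))
  fit2 <- turnbull_npmle(d2, tol = 1e-10)
  expect_equal(fit2$intervals$left, c(1, 3))
  expect_equal(fit2$intervals$right, c(2, 4))
  A2 <- rbind(c(1, 0), c(1, 1), c(1, 1), c(0, 1))
  expect_equal(fit2$intervals$mass, brute_force_em(A2), tolerance = 1e-6)
})

test_that("interval masses are a probability distribution and S is monotone", {
  set.seed(5)
  for (rep in 1:5) {
    tt <- rweibull(60, shape = 1.5, scale = 120)
    d <- ic_from_times(tt, width = 21, horizon = 168)
    fit <- turnbull_npmle(d)
    expect_equal(sum(fit$intervals$mass), 1, tolerance = 1e-8)
    expect_true(all(fit$intervals$mass >= -1e-12))
    grid <- seq(0, 200, by = 7)
    s <- survival_at(fit, grid)
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(survival_at(fit, 0), 1)
  }
})

test_that("survival_at interpolates linearly across non-unique regions", {
  # masses 0.2 at (5,6], 0.6 at (10,20], 0.2 censored beyond 30:
  # S descends 0.8 -> 0.2 across (10, 20]
  d <- ic_intervals(c(5, 10, 10, 10, 30), c(6, 20, 20, 20, Inf))
  fit <- turnbull_npmle(d)
  expect_equal(survival_at(fit, 15), 0.5, tolerance = 1e-7)
  expect_equal(survival_at(fit, 10), 0.8, tolerance = 1e-7)
  expect_equal(survival_at(fit, 20), 0.2, tolerance = 1e-7)
  # median at the interpolated 0.5 crossing
  expect_equal(median_longevity(fit), 15, tolerance = 1e-6)
})

test_that("median follows the strict below-0.5 rule", {
  # step curve: S = 1 on [0,10), 0.4 on [10,20), 0 after
  d <- ic_intervals(rep(c(10, 20), c(6, 4)), rep(c(10, 20), c(6, 4)))
  fit <- turnbull_npmle(d)
  expect_equal(median_longevity(fit), 10, tolerance = 1e-8)
  expect_equal(mean_longevity(fit), 14, tolerance = 1e-6)

  # plateau exactly at 0.5, then a drop: the median is the later drop
  d2 <- ic_intervals(rep(c(10, 30), c(5, 5)), rep(c(10, 30), c(5, 5)))
  fit2 <- turnbull_npmle(d2)
  expect_equal(median_longevity(fit2), 30, tolerance = 1e-8)

  # heavy censoring: curve never below 0.5
  d3 <- ic_intervals(c(0, 50, 50), c(10, Inf, Inf))
  fit3 <- turnbull_npmle(d3)
  expect_warning(m <- median_longevity(fit3), "undefined")
  expect_true(is.na(m))
})

test_that("restricted mean matches closed forms and simulation", {
  # all mass at one point
  fit <- turnbull_npmle(ic_intervals(rep(7, 5), rep(7, 5)))
  expect_equal(mean_longevity(fit), 7, tolerance = 1e-6)

  # n = 2000 exact exponential times: the restricted mean collapses to the
  # sample mean (identity oracle) and lands near the distribution mean
  set.seed(42)
  tt <- rexp(2000, 1 / 100)
  fit2 <- turnbull_npmle(ic_intervals(tt, tt), tol = 1e-10)
  m <- mean_longevity(fit2)
  expect_equal(m, mean(tt), tolerance = 1e-6)
  expect_lt(abs(m - 100), 3 * 100 / sqrt(2000)) # within 3 SE of the truth
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(ic_intervals(numeric(0), numeric(0)), "at least one")
  expect_error(ic_intervals(5, 3), "exceeds")
  expect_error(ic_intervals(Inf, Inf), "finite")
  expect_error(
    turnbull_npmle(ic_intervals(c(0, 0, 0, 3), c(2, 2, 5, 6)),
                   tol = 1e-16, max_iter = 2),
    "converge")
})
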