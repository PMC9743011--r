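# Impedance quantities, Cole-Cole generator, CLAFIC subspace classification.

eis_feature_matrix <- function(eis, quantity = "z_re") {
  samples <- unique(eis$sample_id)
  X <- t(vapply(samples, function(id)
    spectrum_features(eis[eis$sample_id == id, ], quantity),
    spectrum_features(eis[eis$sample_id == samples[1], ], quantity)))
  list(X = X, labels = eis$class[match(samples, eis$sample_id)])
}

test_that("magnitude and loss factor follow their definitions", {
  sp <- eis_spectrum(1000, z_re = 3, z_im = 4)
  expect_equal(sp$magnitude, 5)
  expect_equal(sp$delta, atan(4 / 3))
  sp0 <- eis_spectrum(c(100, 1000), z_re = c(10, 20), z_im = c(0, 0))
  expect_equal(sp0$delta, c(0, 0))
  # |Z| >= |Z_Re| and the loss factor carries the sign of Z_Im
  spn <- eis_spectrum(100, z_re = 10, z_im = -7)
  expect_gte(spn$magnitude, abs(spn$z_re))
  expect_lt(spn$delta, 0)
})

test_that("the Debye curve (alpha = 1) peaks where omega tau equals one", {
  tau <- 1e-4
  f <- exp(seq(log(10), log(1e5), length.out = 2000))
  z <- cole_cole_impedance(f, r_inf = 100, r0 = 1100, tau = tau, alpha = 1)
  f_peak <- f[which.max(-Im(z))]
  expect_equal(2 * pi * f_peak * tau, 1, tolerance = 0.01)
  # real part descends from r0 to r_inf
  expect_equal(Re(z)[1], 1100, tolerance = 0.01)
  expect_lt(abs(Re(z)[length(f)] - 100), 5)
  expect_error(cole_cole_impedance(f, 100, 1100, tau, alpha = 1.2), "alpha")
  expect_error(cole_cole_impedance(f, 1100, 100, tau), "r0 > r_inf")
})

test_that("noise-free spectra are identical within class and distinct between", {
  p <- eis_sim_params(noise_sd = 0, seed = 2)
  eis <- simulate_eis(p)
  cool <- eis[eis$class == "Cool", ]
  first <- cool[cool$sample_id == cool$sample_id[1], "z_re"]
  for (id in unique(cool$sample_id)) {
    expect_equal(cool[cool$sample_id == id, "z_re"], first)
  }
  warm <- eis[eis$class == "Warm" & eis$sample_id == "Warm_01", "z_re"]
  expect_gt(max(abs(warm - first)), 1)
})

test_that("features are unit-norm, windowed, and scale-invariant", {
  p <- eis_sim_params(seed = 4)
  eis <- simulate_eis(p)
  one <- eis[eis$sample_id == "Cool_01", ]
  x <- spectrum_features(one, "z_re")
  expect_equal(sum(x^2), 1, tolerance = 1e-12)
  expect_equal(length(x), sum(p$frequencies >= 150 & p$frequencies <= 150e3))
  scaled <- one
  scaled$z_re <- one$z_re * 10
  expect_equal(spectrum_features(scaled, "z_re"), x, tolerance = 1e-12)
  expect_error(spectrum_features(one, "z_re", window = c(1e7, 2e7)), "window")
})

test_that("subspace bases are orthonormal and identical vectors give k = 1", {
  v <- c(3, 4, 0, 0)
  X <- rbind(v, v, v)
  m <- clafic_fit(X, rep("a", 3), k = 1)
  expect_equal(abs(as.vector(m$bases$a)), abs(v / 5), tolerance = 1e-10)

  set.seed(12)
  Xr <- matrix(rnorm(80), 10, 8)
  for (k in c(1, 3, 5)) {
    mr <- clafic_fit(Xr, rep(c("a", "b"), each = 5), k = k)
    for (B in mr$bases) {
      expect_equal(crossprod(B), diag(k), tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
  expect_error(clafic_fit(Xr, rep(c("a", "b"), each = 5), k = 6), "fewer than")
  # k = 1 on a symmetric two-vector class: leading eigenvector of the
  # second-moment matrix, computed with an independent eigen call
  Y <- rbind(c(1, 0.2), c(0.2, 1))
  Yn <- Y / sqrt(rowSums(Y^2))
  m2 <- clafic_fit(Y, c("a", "a"), k = 1)
  ev <- eigen(t(Yn) %*% Yn / 2)$vectors[, 1]
  expect_equal(abs(as.vector(m2$bases$a)), abs(ev), tolerance = 1e-10)
})

test_that("classification follows projection lengths with flagged ties", {
  # class A spans e1, class B spans e2; e1 belongs to A with projections (1, 0)
  X <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  m <- clafic_fit(X, c("A", "A", "B", "B"), k = 1)
  r <- clafic_classify(m, c(1, 0, 0))
  expect_equal(r$class, "A")
  expect_equal(unname(r$projection), c(1, 0), tolerance = 1e-12)
  expect_false(r$ambiguous)
  # projections of unit vectors lie in [0, 1]
  expect_true(all(r$projection >= 0 & r$projection <= 1))
  # k equal to the full feature dimension: all projections 1, ambiguous
  e <- diag(3)
  X9 <- rbind(e[1, ] + 0.1 * e[2, ], e[1, ], e[1, ] + 0.1 * e[3, ],
              e[2, ] + 0.1 * e[3, ], e[2, ], e[2, ] + 0.1 * e[1, ],
              e[3, ] + 0.1 * e[1, ], e[3, ], e[3, ] + 0.1 * e[2, ])
  m3 <- clafic_fit(X9, rep(c("A", "B", "C"), each = 3), k = 3)
  r3 <- clafic_classify(m3, c(0.5, 0.5, 0.7))
  expect_true(r3$ambiguous)
  expect_equal(unname(r3$projection), rep(1, 3), tolerance = 1e-10)
})

test_that("own-class projection length never decreases with k", {
  set.seed(31)
  X <- matrix(rnorm(60), 12, 5)
  lab <- rep(c("a", "b"), each = 6)
  Xn <- X / sqrt(rowSums(X^2))
  for (i in 1:12) {
    projs <- vapply(1:5, function(k) {
      m <- clafic_fit(X, lab, k)
      clafic_classify(m, X[i, ])$projection[[lab[i]]]
    }, numeric(1))
    expect_true(all(diff(projs) >= -1e-10))
  }
})

test_that("four Cole-Cole classes classify perfectly; shuffles are at chance", {
  eis <- simulate_eis(eis_sim_params(seed = 8))
  fm <- eis_feature_matrix(eis, "z_re")
  ev <- clafic_evaluate(fm$X, fm$labels, k_range = 1:6)
  expect_equal(ev$success$leave_one_out, rep(1, 6))
  expect_equal(ev$success$resubstitution, rep(1, 6))
  expect_false(any(ev$success$degenerate))
  # the loss factor separates the classes too
  fmd <- eis_feature_matrix(eis, "delta")
  evd <- clafic_evaluate(fmd$X, fmd$labels, k_range = 2)
  expect_equal(evd$success$leave_one_out, 1)
  # shuffled labels drop success to roughly 1 / n_classes
  set.seed(5)
  sh <- mean(replicate(8, {
    clafic_evaluate(fm$X, sample(fm$labels), k_range = 3)$success$leave_one_out
  }))
  expect_lt(abs(sh - 0.25), 0.12)
})
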