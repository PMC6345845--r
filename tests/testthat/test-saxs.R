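test_that("Debye intensity reproduces closed forms and the double-loop oracle", {
  q <- seq(0, 0.5, length.out = 21)
  one <- matrix(0, 1, 3)
  expect_equal(debye_intensity(one, q, form_factors = 2)$intensity,
               rep(4, length(q)))

  two <- pair_coords(10)
  got <- debye_intensity(two, q)$intensity
  ref <- ifelse(q == 0, 4, 2 * (1 + sin(10 * q) / (10 * q)))
  expect_equal(got, ref, tolerance = 1e-12)

  set.seed(13)
  xyz <- matrix(rnorm(24, sd = 8), 8, 3)
  f <- runif(8, 0.5, 2)
  got <- debye_intensity(xyz, q, form_factors = f)$intensity
  expect_equal(got, debye_oracle(xyz, q, f), tolerance = 1e-10)

  # I(0) = (sum f)^2 exactly
  expect_equal(got[1], sum(f)^2, tolerance = 1e-12)
  expect_error(debye_intensity(matrix(0, 0, 3), q), "empty")
})

test_that("Debye intensity is invariant under global rigid motions", {
  set.seed(14)
  xyz <- matrix(rnorm(60, sd = 10), 20, 3)
  q <- seq(0.01, 0.4, length.out = 30)
  base <- debye_intensity(xyz, q)$intensity
  for (rep in 1:3) {
    moved <- debye_intensity(random_rigid_transform(xyz), q)$intensity
    expect_equal(moved / base, rep(1, length(q)), tolerance = 1e-9)
  }
})

test_that("chi-square fitting finds the analytic optimal scale", {
  q <- seq(0.01, 0.3, length.out = 50)
  i <- 100 * exp(-q^2 * 100)
  target <- saxs_profile(q, i, sigma = rep(1, 50))
  fit <- chi2_fit(target, saxs_profile(q, i))
  expect_equal(fit$a, 1)
  expect_equal(fit$chi2, 0)
  fit2 <- chi2_fit(target, saxs_profile(q, 2 * i))
  expect_equal(fit2$a, 0.5)
  expect_equal(fit2$chi2, 0, tolerance = 1e-12)
  expect_error(chi2_fit(target, saxs_profile(q, rep(0, 50))), "all-zero")
  expect_error(chi2_fit(saxs_profile(q, i), saxs_profile(q, i)), "sigma")
})

test_that("the closed-form scale beats any sampled alternative", {
  set.seed(15)
  for (rep in 1:20) {
    q <- sort(runif(50, 0.01, 0.4))
    ie <- runif(50, 1, 100)
    im <- runif(50, 1, 100)
    sig <- runif(50, 0.5, 5)
    target <- saxs_profile(q, ie, sig)
    fit <- chi2_fit(target, saxs_profile(q, im))
    # dense grid search around the optimum
    grid <- seq(0.2, 5, length.out = 20001) * fit$a
    chi2g <- vapply(grid, function(a) sum((ie - a * im)^2 / sig^2) / 50,
                    numeric(1))
    expect_equal(fit$chi2, min(chi2g), tolerance = 1e-6)
    expect_true(all(fit$chi2 <= chi2g + 1e-12))
  }
})

test_that("Guinier analysis recovers known radii of gyration", {
  # noiseless synthetic profile with Rg = 43 A
  q <- seq(0.005, 0.12, length.out = 100)
  prof <- saxs_profile(q, 100 * exp(-q^2 * 43^2 / 3))
  g <- guinier_fit(prof)
  expect_equal(g$rg, 43, tolerance = 1e-3)
  expect_equal(g$i0, 100, tolerance = 1e-3)
  expect_lte(q[g$window[2]] * g$rg, 1.3 + 1e-9)

  # Debye profile of a dense uniform-sphere bead model, R = 30 A
  pts <- lattice_sphere(30)
  prof2 <- debye_intensity(pts, seq(0.004, 0.08, length.out = 30))
  g2 <- guinier_fit(prof2)
  expect_equal(g2$rg, sqrt(3 / 5) * 30, tolerance = 0.02)
  # and agrees with the direct coordinate Rg within 3%
  expect_equal(g2$rg, radius_of_gyration(pts), tolerance = 0.03)

  # no valid window when qmin * Rg is already too large
  qh <- seq(0.05, 0.3, length.out = 40)
  big <- saxs_profile(qh, exp(-qh^2 * 80^2 / 3))
  expect_error(guinier_fit(big), "window")
})

test_that("ensemble intensity is the pointwise weighted mean", {
  q <- seq(0.01, 0.2, length.out = 10)
  p1 <- saxs_profile(q, rep(1, 10))
  p3 <- saxs_profile(q, rep(3, 10))
  expect_equal(ensemble_intensity(list(p1), 1)$intensity, p1$intensity)
  expect_equal(ensemble_intensity(list(p1, p1), c(0.5, 0.5))$intensity,
               p1$intensity)
  expect_equal(ensemble_intensity(list(p1, p3), c(0.5, 0.5))$intensity,
               rep(2, 10))
  expect_error(ensemble_intensity(list(p1, p3), 1), "length")
  expect_error(ensemble_intensity(list(p1, p3), c(0.9, 0.2)), "sum")
})

test_that("profile container and interpolation enforce their contracts", {
  expect_error(saxs_profile(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(saxs_profile(c(-0.1, 0.1), c(1, 1)), ">= 0")
  expect_error(saxs_profile(c(0.1, 0.2), c(1, 1), c(1, -1)), "sigma")
  p <- saxs_profile(seq(0.1, 0.2, by = 0.01), 1:11)
  expect_error(interpolate_intensity(p, c(0.05, 0.15)), "extrapolation")
  expect_equal(interpolate_intensity(p, 0.155), 6.5)
})
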