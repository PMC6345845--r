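make_profile_pool <- function(n = 20, nq = 40, seed = 1) {
  set.seed(seed)
  q <- seq(0.01, 0.3, length.out = nq)
  rg <- runif(n, 15, 45)
  im <- t(sapply(rg, function(r) 100 * exp(-q^2 * r^2 / 3) *
                   (1 + 0.05 * sin(40 * q * r / 30))))
  attr(im, "q") <- q
  list(q = q, im = im)
}

test_that("ranking puts the generating structure first and respects scale freedom", {
  pp <- make_profile_pool()
  target <- saxs_profile(pp$q, pp$im[7, ], sigma = 0.01 * pp$im[7, ])
  ranked <- rank_structures(pp$im, target)
  expect_equal(ranked$id[1], 7)
  expect_equal(ranked$chi2[1], 0, tolerance = 1e-20)
  expect_false(is.unsorted(ranked$chi2))

  # a profile proportional to the target ties the exact one at chi2 = 0
  im3 <- rbind(pp$im[7, ], pp$im[8, ] * 1.1, 2 * pp$im[7, ])
  attr(im3, "q") <- pp$q
  r3 <- rank_structures(im3, target)
  expect_equal(r3$chi2[1:2], c(0, 0), tolerance = 1e-16)
  expect_equal(r3$id[1:2], c(1, 3))    # tie broken by pool id
  expect_equal(r3$a[r3$id == 3], 0.5, tolerance = 1e-12)
})

test_that("ranking agrees with independent per-structure fits", {
  pp <- make_profile_pool(seed = 3)
  set.seed(4)
  target <- saxs_profile(pp$q, pp$im[2, ] * (1 + rnorm(length(pp$q), 0, 0.02)),
                         sigma = 0.02 * pp$im[2, ])
  ranked <- rank_structures(pp$im, target)
  solo <- vapply(seq_len(nrow(pp$im)), function(k) {
    chi2_fit(target, saxs_profile(pp$q, pp$im[k, ]))$chi2
  }, numeric(1))
  expect_equal(ranked$chi2, solo[ranked$id], tolerance = 1e-10)
  expect_equal(ranked$id, order(solo))
})

test_that("top-N selection returns the N best and validates n", {
  pp <- make_profile_pool()
  target <- saxs_profile(pp$q, pp$im[5, ], sigma = 0.01 * pp$im[5, ] + 0.1)
  ranked <- rank_structures(pp$im, target)
  expect_equal(sort(select_top_n(ranked, nrow(pp$im))), seq_len(nrow(pp$im)))
  expect_equal(select_top_n(ranked, 1), 5)
  top5 <- select_top_n(ranked, 5)
  worst_kept <- max(ranked$chi2[match(top5, ranked$id)])
  expect_true(all(ranked$chi2[!(ranked$id %in% top5)] >= worst_kept))
  expect_error(select_top_n(ranked, 0), "positive")
  expect_error(select_top_n(ranked, 99), "exceeds")
})

test_that("minimum ensemble degenerates to the best single structure", {
  pp <- make_profile_pool(seed = 6)
  target <- saxs_profile(pp$q, pp$im[11, ], sigma = 0.01 * pp$im[11, ])
  ens <- minimum_ensemble(pp$im, target, max_size = 1, chi2_accept = 1.5)
  ranked <- rank_structures(pp$im, target)
  expect_equal(ens$size, 1)
  expect_equal(ens$members, ranked$id[1])
  expect_equal(ens$chi2, ranked$chi2[1], tolerance = 1e-12)
  expect_true(ens$reached)
  expect_equal(ens$weights, 1)
})

test_that("the two-state fixture is solved by the true pair and no single structure", {
  fx <- two_state_fixture(seed = 17, n_pool = 120)
  im <- pool_intensities(fx$pool, fx$target$q)
  ens <- minimum_ensemble(im, fx$target, max_size = 2, chi2_accept = 1.5)
  expect_equal(ens$size, 2)
  expect_equal(ens$members, fx$truth)
  expect_equal(ens$weights, c(0.5, 0.5))
  expect_lt(ens$chi2, 1.5)
  expect_true(ens$reached)
  # no single structure reaches the acceptance threshold
  best_single <- rank_structures(im, fx$target)$chi2[1]
  expect_gt(best_single, 1.8)
  # exhaustive-enumeration oracle over all pairs
  n <- nrow(im)
  best <- c(Inf, 0, 0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    f <- chi2_fit(fx$target, saxs_profile(fx$target$q, (im[i, ] + im[j, ]) / 2))
    if (f$chi2 < best[1]) best <- c(f$chi2, i, j)
  }
  expect_equal(sort(ens$members), sort(best[2:3]))
  expect_equal(ens$chi2, best[1], tolerance = 1e-10)
})

test_that("the best ensemble chi-square never increases with allowed size", {
  fx <- two_state_fixture(seed = 23, n_pool = 60)
  im <- pool_intensities(fx$pool, fx$target$q)
  chis <- vapply(1:3, function(s) {
    minimum_ensemble(im, fx$target, max_size = s, chi2_accept = 0,
                     prune = 40)$chi2
  }, numeric(1))
  expect_true(all(diff(chis) <= 1e-12))
})

test_that("non-negative least-squares weights recover a known mixture", {
  fx <- two_state_fixture(seed = 29, n_pool = 30)
  im <- pool_intensities(fx$pool, fx$target$q)
  # restricted to the true pair, NNLS must find the 50/50 mixture
  im_truth <- im[fx$truth, , drop = FALSE]
  attr(im_truth, "q") <- fx$target$q
  ens <- minimum_ensemble(im_truth, fx$target, max_size = 2,
                          chi2_accept = 1.5, mode = "nnls")
  expect_equal(sort(ens$members), fx$truth)
  expect_equal(ens$weights, c(0.5, 0.5), tolerance = 0.1)
  expect_true(all(ens$weights >= 0))
  # with free weights the fit can only improve on the equal-weight one
  eq <- minimum_ensemble(im, fx$target, max_size = 2, chi2_accept = 0)
  nn <- minimum_ensemble(im, fx$target, max_size = 2, chi2_accept = 0,
                         mode = "nnls")
  expect_lte(nn$chi2, eq$chi2 + 1e-9)
})
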