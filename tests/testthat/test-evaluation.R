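test_that("bias and imprecision match hand arithmetic and loop oracles", {
  p <- prediction_pairs(c(12, 18), c(10, 22))
  expect_equal(mean_error(p), -1)
  p2 <- prediction_pairs(c(10, 24), c(8, 22))
  expect_equal(mape(p2), 100 * mean(c(2 / 8, 2 / 22)), tolerance = 1e-12)

  # perfect predictions
  p0 <- prediction_pairs(c(5, 9, 30), c(5, 9, 30))
  expect_equal(mean_error(p0), 0)
  expect_equal(mape(p0), 0)

  # ME shift-linearity and MAPE scale invariance
  set.seed(41)
  pred <- runif(50, 5, 60)
  obs <- runif(50, 5, 60)
  pp <- prediction_pairs(pred, obs)
  expect_equal(mean_error(prediction_pairs(pred + 3, obs)),
               mean_error(pp) + 3, tolerance = 1e-12)
  expect_equal(mape(prediction_pairs(2.5 * pred, 2.5 * obs)), mape(pp),
               tolerance = 1e-12)

  # loop-based oracles
  me_loop <- 0
  mape_loop <- 0
  for (i in seq_along(pred)) {
    me_loop <- me_loop + (pred[i] - obs[i]) / length(pred)
    mape_loop <- mape_loop + abs(pred[i] - obs[i]) / obs[i] / length(pred)
  }
  expect_equal(mean_error(pp), me_loop, tolerance = 1e-12)
  expect_equal(mape(pp), 100 * mape_loop, tolerance = 1e-12)

  # censored pairs are excluded but counted
  pc <- prediction_pairs(c(12, 18, 1), c(10, 22, 1.5), c(FALSE, FALSE, TRUE))
  expect_equal(mean_error(pc), -1)
  expect_equal(pc$n_censored, 1)

  expect_error(mean_error(prediction_pairs(numeric(0), numeric(0))), "no prediction")
  expect_error(mape(prediction_pairs(1, 0)), "non-positive")
})

test_that("Bland-Altman analysis reports classic and regression-based limits", {
  # identical series: zero difference, zero-width limits
  x <- c(1, 5, 9, 14)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$loa_upper - ba0$loa_lower, 0)

  # closed-form: d = (0, 2, 0, 2) against varying averages with no trend
  y <- c(1, 3, 9, 12)
  x2 <- y + c(0, 2, 0, 2)
  ba <- bland_altman(x2, y)
  expect_equal(ba$mean_difference, 1)
  expect_equal(ba$sd_difference, sd(c(0, 2, 0, 2)))
  expect_equal(ba$loa_lower, 1 - 1.96 * ba$sd_difference, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1 + 1.96 * ba$sd_difference, tolerance = 1e-12)

  # proportional bias x = 1.2 y switches to regression-based limits
  set.seed(43)
  yb <- runif(60, 10, 100)
  xb <- 1.2 * yb + rnorm(60, 0, 0.5)
  bab <- bland_altman(xb, yb)
  expect_identical(bab$mode, "regression")
  expect_lt(bab$slope_p, 0.05)
  expect_true(all(c("band_lower", "band_upper") %in% names(bab$data)))

  # no trend: classic mode retained
  ba_flat <- bland_altman(yb + rnorm(60, 1, 0.5), yb)
  expect_identical(ba_flat$mode, "classic")

  # degenerate averages force classic mode instead of a regression error
  ba_const <- bland_altman(c(4, 6, 4, 6), c(6, 4, 6, 4))
  expect_identical(ba_const$mode, "classic")
  expect_true(is.na(ba_const$slope))

  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("classic limits of agreement cover ~95% of Gaussian differences", {
  set.seed(47)
  n <- 1e4
  x <- rnorm(n, 50, 5)
  y <- x - rnorm(n, 2, 3) # pure additive disagreement
  ba <- bland_altman(x, y)
  d <- x - y
  cover <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("engine comparison reproduces exact rank tests and correlation", {
  # exact signed-rank p at n = 6 against full sign-pattern enumeration
  x <- c(10.2, 13.5, 9.1, 17.8, 12.0, 15.3)
  y <- c(9.0, 14.9, 8.1, 15.2, 13.45, 14.0) # distinct |differences|, no zeros
  rep6 <- compare_engines(list(q = list(x = x, y = y, paired = TRUE)))
  expect_equal(rep6$p_value, signed_rank_p_enum(x - y), tolerance = 1e-12)

  # exact and approximate p agree within 0.01 at n = 25
  set.seed(53)
  x25 <- rnorm(25, 10, 2)
  y25 <- x25 + rnorm(25, 0.4, 1)
  p_exact <- suppressWarnings(wilcox.test(x25, y25, paired = TRUE,
                                          exact = TRUE))$p.value
  p_approx <- suppressWarnings(wilcox.test(x25, y25, paired = TRUE,
                                           exact = FALSE,
                                           correct = TRUE))$p.value
  expect_lt(abs(p_exact - p_approx), 0.01)

  # identical paired lists: test undefined, flagged as such
  same <- compare_engines(list(q = list(x = x, y = x, paired = TRUE)))
  expect_true(is.na(same$p_value))
  expect_match(same$note, "undefined")

  # perfectly correlated estimates
  lin <- compare_engines(list(q = list(x = x, y = 2 * x + 1, paired = FALSE)))
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_identical(lin$test, "mann_whitney")
})

test_that("target attainment uses strict inequalities and valid fractions", {
  t0 <- target_attainment(rep(666, 4), rep(24.3, 4))
  expect_equal(t0$underexposed, 0)
  expect_equal(t0$overexposed, 0)

  t1 <- target_attainment(c(600, 700, 800), c(10, 30, 20))
  expect_equal(t1$underexposed, 1 / 3)
  expect_equal(t1$overexposed, 1 / 3)

  set.seed(59)
  auc <- runif(40, 300, 1500)
  cmin <- runif(40, 5, 40)
  perm <- sample(40)
  ta <- target_attainment(auc, cmin)
  tb <- target_attainment(auc[perm], cmin[perm])
  expect_equal(ta$underexposed, tb$underexposed)
  expect_true(ta$underexposed >= 0 && ta$underexposed <= 1)
})
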