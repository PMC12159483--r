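test_that("exact linear decay is fitted perfectly at zero order", {
  s <- storage_series("x", 5, 0:5 * 3, 10 - 0.5 * (0:5 * 3))
  f <- fit_order(s, 0)
  expect_equal(f$k, 0.5, tolerance = 1e-12)
  expect_equal(f$c0_fit, 10, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$direction, "decreasing")
  expect_equal(f$chi_square, 0, tolerance = 1e-20)
})

test_that("lipid-oxidation series reproduce the published zero-order rates", {
  fx <- lassi_fixtures()
  k5 <- fit_order(fx$storage[["tba@5"]], 0)$k
  k25 <- fit_order(fx$storage[["tba@25"]], 0)$k
  expect_equal(round(k5, 4), 0.0016)
  expect_equal(round(k25, 4), 0.0027)
  expect_equal(fit_order(fx$storage[["tba@5"]], 0)$direction, "increasing")
})

test_that("fitted slopes match the closed-form OLS oracle to 1e-12", {
  fx <- lassi_fixtures()
  for (s in fx$storage) {
    f0 <- fit_order(s, 0)
    expect_equal(f0$k, abs(slope_oracle(s$days, s$values)),
                 tolerance = 1e-12)
    f1 <- fit_order(s, 1)
    expect_equal(f1$k, abs(slope_oracle(s$days, log(s$values))),
                 tolerance = 1e-12)
    f2 <- fit_order(s, 2)
    expect_equal(f2$k, abs(slope_oracle(s$days, 1 / s$values)),
                 tolerance = 1e-12)
  }
})

test_that("reduced chi-square follows the offset algebra and order ranking", {
  s <- storage_series("x", 5, c(0, 3, 6, 9, 12, 15),
                      10 - 0.4 * c(0, 3, 6, 9, 12, 15))
  f <- fit_order(s, 0)
  eps <- 0.05
  n <- length(s$values)
  shifted <- f
  shifted$fitted <- f$fitted + eps
  expect_equal(chi_square(shifted, s), n * eps^2 / (n - 2),
               tolerance = 1e-12)
  fx <- lassi_fixtures()
  tba5 <- fx$storage[["tba@5"]]
  chi0 <- fit_order(tba5, 0)$chi_square
  chi1 <- fit_order(tba5, 1)$chi_square
  expect_gt(chi0, 0)
  expect_lt(chi0, chi1)
})

test_that("order selection identifies the generating law", {
  t <- seq(0, 15, by = 3)
  s0 <- storage_series("z", 5, t, 10 - 0.4 * t)
  sel0 <- select_order(s0)
  expect_equal(sel0$best_order, 0)
  expect_equal(sel0$best_fit$r2, 1, tolerance = 1e-12)
  # exact first-order with k*t spanning > 1
  s1 <- storage_series("f", 5, t, 10 * exp(-0.1 * t))
  expect_equal(select_order(s1)$best_order, 1)
  # exact second-order
  s2 <- storage_series("s", 5, t, 1 / (1 / 10 + 0.05 * t))
  expect_equal(select_order(s2)$best_order, 2)
  # the fixture lipid series are best described by zero order
  fx <- lassi_fixtures()
  expect_equal(select_order(fx$storage[["tba@5"]])$best_order, 0)
})

test_that("half-life formulas reproduce the published stability summaries", {
  expect_equal(round(half_life(8.29, 0.0694, 0), 2), 59.73)
  expect_equal(round(half_life(8.29, 0.1279, 0), 2), 32.41)
  expect_equal(round(half_life(3.07, 0.1646, 0), 2), 9.33)
  expect_equal(round(half_life(0.42, 0.0191, 0), 2), 10.99)
  expect_equal(half_life(8.29, 2 * 0.0694, 0),
               half_life(8.29, 0.0694, 0) / 2, tolerance = 1e-12)
  expect_equal(half_life(10, 0.1, 1), log(2) / 0.1, tolerance = 1e-12)
  expect_equal(half_life(10, 0.1, 2), 1, tolerance = 1e-12)
  expect_message(expect_identical(half_life(1, 0, 0), Inf), "infinite")
})

test_that("zero-order k scales linearly with a uniform unit rescale", {
  fx <- lassi_fixtures()
  s <- fx$storage[["ffa@5"]]
  s_scaled <- storage_series(s$index_name, s$temperature, s$days,
                             1000 * s$values, direction = s$direction)
  expect_equal(fit_order(s_scaled, 0)$k, 1000 * fit_order(s, 0)$k,
               tolerance = 1e-9)
  # first-order k is invariant under the same rescale
  expect_equal(fit_order(s_scaled, 1)$k, fit_order(s, 1)$k,
               tolerance = 1e-12)
})

test_that("degenerate series and transforms are rejected", {
  expect_error(storage_series("x", 5, c(0, 3), c(1, 2)), "at least 3")
  expect_error(storage_series("x", 5, c(1, 3, 6), c(1, 2, 3)), "start at 0")
  expect_error(storage_series("x", 5, c(0, 3, 3), c(1, 2, 3)),
               "strictly increasing")
  neg <- storage_series("x", 5, c(0, 3, 6), c(2, 0.5, -1))
  expect_error(fit_order(neg, 1), "strictly positive")
  expect_error(fit_order(neg, 2), "strictly positive")
  expect_error(fit_order(storage_series("x", 5, c(0, 3, 6), 1:3), 3),
               "order must be")
})
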