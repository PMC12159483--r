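test_that("noiseless Arrhenius data are recovered exactly", {
  k_ref <- 0.08
  Ea <- 1.8e4
  temps <- c(5, 15, 25)
  TK <- temps + 273.15
  k <- k_ref * exp(-(Ea / 8.314) * (1 / TK - 1 / (15 + 273.15)))
  fit <- fit_arrhenius(k, temps)
  expect_equal(fit$Ea, Ea, tolerance = 1e-10)
  expect_equal(fit$k_ref, k_ref, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(predict_k(fit, temps), k, tolerance = 1e-12)
  expect_equal(predict_k(fit, fit$t_ref_c), fit$k_ref, tolerance = 1e-12)
})

test_that("identical rates give zero activation energy and a flat prediction", {
  fit <- fit_arrhenius(c(0.2, 0.2, 0.2), c(5, 15, 25))
  expect_equal(fit$Ea, 0, tolerance = 1e-10)
  expect_equal(fit$k_ref, 0.2, tolerance = 1e-12)
  expect_equal(predict_k(fit, 40), 0.2, tolerance = 1e-12)
})

test_that("acceptability rates give the expected activation energy", {
  fit <- fit_arrhenius(c(0.0694, 0.0815, 0.1279), c(5, 15, 25))
  # independent least-squares oracle gives 2.0952e4 J/mol
  expect_equal(fit$Ea, 2.0952e4, tolerance = 1e-3)
  expect_true(fit$Ea > 0)
})

test_that("temperature regressions match the normal-equations oracle", {
  fx <- lassi_fixtures()
  for (idx in unique(fx$rates$index_name)) {
    sub <- fx$rates[fx$rates$index_name == idx & fx$rates$order == 0, ]
    TK <- sub$temperature_C + 273.15
    # Arrhenius
    x <- 1 / TK - 1 / mean(TK)
    X <- cbind(1, x)
    beta <- ols_oracle(X, log(sub$k))
    ar <- fit_arrhenius(sub$k, sub$temperature_C)
    expect_equal(ar$Ea, -beta[2] * 8.314, tolerance = 1e-12)
    expect_equal(ar$k_ref, exp(beta[1]), tolerance = 1e-12)
    # Eyring (per-second rates)
    Xe <- cbind(1, 1 / TK)
    be <- ols_oracle(Xe, log(sub$k / 86400 / TK))
    ey <- fit_eyring(sub$k, sub$temperature_C)
    expect_equal(ey$delta_H, -be[2] * 8.314, tolerance = 1e-9)
    expect_equal(ey$delta_S, 8.314 * (be[1] - log(1.381e-23 / 6.626e-34)),
                 tolerance = 1e-9)
    # Ball
    Xb <- cbind(1, sub$temperature_C - mean(sub$temperature_C))
    bb <- ols_oracle(Xb, log10(log(10) / sub$k))
    ba <- fit_ball(sub$k, sub$temperature_C)
    expect_equal(ba$Z, -1 / bb[2], tolerance = 1e-9)
    expect_equal(ba$D_ref, 10^bb[1], tolerance = 1e-9)
  }
})

test_that("Eyring enthalpy tracks Ea minus RT over a narrow range", {
  k <- c(0.0694, 0.0815, 0.1279)
  temps <- c(5, 15, 25)
  ar <- fit_arrhenius(k, temps)
  ey <- fit_eyring(k, temps)
  expect_equal(ey$delta_H, ar$Ea - 8.314 * mean(temps + 273.15),
               tolerance = 0.01)
})

test_that("activation entropy is negative for all six fixture indices", {
  fx <- lassi_fixtures()
  dS <- vapply(unique(fx$rates$index_name), function(idx) {
    sub <- fx$rates[fx$rates$index_name == idx & fx$rates$order == 0, ]
    fit_eyring(sub$k, sub$temperature_C)$delta_S
  }, numeric(1L))
  expect_length(dS, 6L)
  expect_true(all(dS < 0))
})

test_that("D and Z values follow their closed forms", {
  expect_equal(d_value(log(10)), 1, tolerance = 1e-12)
  expect_equal(d_value(0.1646), 13.99, tolerance = 1e-3)
  k <- c(0.02, 0.11)
  expect_equal(d_value(k) * k, rep(log(10), 2), tolerance = 1e-12)
  # two-point Ball line is analytic
  k2 <- c(0.05, 0.2)
  t2 <- c(5, 25)
  ba <- fit_ball(k2, t2)
  D <- log(10) / k2
  expect_equal(ba$Z, (t2[2] - t2[1]) / log10(D[1] / D[2]), tolerance = 1e-9)
  # D halving every +10 degC gives Z = 10 / log10(2)
  temps <- c(5, 15, 25)
  D3 <- 40 * 0.5^((temps - 5) / 10)
  ba3 <- fit_ball(log(10) / D3, temps)
  expect_equal(ba3$Z, 10 / log10(2), tolerance = 1e-9)
  expect_gt(ba3$Z, 0)
})

test_that("Arrhenius and Ball agree on exact Arrhenius data at interior temperatures", {
  k_ref <- 0.1
  Ea <- 1.5e4
  temps <- c(5, 15, 25)
  TK <- temps + 273.15
  k <- k_ref * exp(-(Ea / 8.314) * (1 / TK - 1 / (15 + 273.15)))
  ar <- fit_arrhenius(k, temps)
  ba <- fit_ball(k, temps)
  for (tt in c(8, 12, 15, 18, 22)) {
    D_ar <- log(10) / predict_k(ar, tt)
    D_ba <- ba$D_ref * 10^(-(tt - ba$t_ref_c) / ba$Z)
    expect_equal(D_ba / D_ar, 1, tolerance = 0.02)
  }
})

test_that("rate-table validation rejects degenerate inputs", {
  expect_error(fit_arrhenius(0.1, 5), "2 distinct temperatures")
  expect_error(fit_arrhenius(c(0.1, 0.2), c(5, 5)), "distinct")
  expect_error(fit_arrhenius(c(0.1, -0.2), c(5, 25)), "positive")
  expect_error(predict_k(fit_arrhenius(c(0.1, 0.2), c(5, 25)), -300),
               "absolute zero")
  expect_error(d_value(0), "positive")
})
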