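test_that("pseudo-component coding maps bounds and optimum correctly", {
  expect_equal(unname(to_pseudo(c(9.189, 60, 15.311), lassi_spec)),
               c((9.189 - 5) / 4.5, 0, 0.311 / 4.5), tolerance = 1e-12)
  expect_equal(unname(to_pseudo(c(9.5, 60, 15), lassi_spec)), c(1, 0, 0))
  expect_equal(unname(from_pseudo(c(1, 0, 0), lassi_spec)), c(9.5, 60, 15))
  expect_equal(unname(from_pseudo(c(0.93088889, 0, 0.06911111), lassi_spec)),
               c(9.189, 60, 15.311), tolerance = 1e-7)
})

test_that("pseudo round-trip is the identity on random feasible points", {
  set.seed(42)
  pts <- random_feasible(1000)
  pseudo <- to_pseudo(pts, lassi_spec)
  expect_true(all(abs(rowSums(pseudo) - 1) < 1e-9))
  expect_true(all(pseudo >= 0 & pseudo <= 1))
  back <- from_pseudo(pseudo, lassi_spec)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("invalid amounts are rejected with the offending component named", {
  expect_error(to_pseudo(c(9.5, 60, 16), lassi_spec), "sum to 84.5")
  expect_error(to_pseudo(c(4, 61, 19.5), lassi_spec), "juice")
  expect_error(to_pseudo(c(5, 65, 14.5), lassi_spec), "dahi")
  expect_error(from_pseudo(c(0.7, 0.2, 0.2), lassi_spec), "sum to 1")
  expect_error(mixture_design_spec(c("a", "b"), c(50, 50), c(60, 60), 90),
               "infeasible")
})

test_that("scheffe_terms expands vertices, centroid and interior points", {
  expect_equal(unname(scheffe_terms(c(1, 0, 0), "special_cubic")),
               c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(scheffe_terms(rep(1 / 3, 3), "special_cubic")),
               c(1/3, 1/3, 1/3, 1/9, 1/9, 1/9, 1/27), tolerance = 1e-12)
  tm <- scheffe_terms(c(0.93089, 0, 0.06911), "special_cubic")
  expect_equal(unname(tm["AC"]), 0.93089 * 0.06911, tolerance = 1e-12)
  expect_true(all(tm[c("B", "AB", "BC", "ABC")] == 0))
  expect_named(scheffe_terms(c(0.5, 0.3, 0.2), "linear"), c("A", "B", "C"))
  expect_length(scheffe_terms(c(0.5, 0.3, 0.2), "quadratic"), 6L)
})

test_that("zero-noise fits recover known coefficients at every degree", {
  design <- lassi_design_runs()[, c("run", "juice", "dahi", "water")]
  truth <- list(linear = c(5, -2, 7),
                quadratic = c(5, -2, 7, 1.5, -0.5, 2),
                special_cubic = c(5, -2, 7, 1.5, -0.5, 2, -10))
  for (deg in names(truth)) {
    pseudo <- to_pseudo(design[, c("juice", "dahi", "water")], lassi_spec)
    design$y <- drop(scheffe_terms(pseudo, deg) %*% truth[[deg]])
    fit <- fit_scheffe(design, "y", lassi_spec, degree = deg)
    expect_equal(unname(coef <- fit$model$coefficients), truth[[deg]],
                 tolerance = 1e-8)
    expect_equal(fit$stats$r2, 1, tolerance = 1e-10)
    expect_lt(fit$stats$root_mse, 1e-8)
  }
})

test_that("fitted coefficients match the normal-equations oracle", {
  set.seed(7)
  design <- lassi_design_runs()[, c("juice", "dahi", "water")]
  pseudo <- to_pseudo(design, lassi_spec)
  X <- scheffe_terms(pseudo, "special_cubic")
  for (rep_i in 1:5) {
    design$y <- rnorm(nrow(design), mean = 10, sd = 2)
    fit <- fit_scheffe(design, "y", lassi_spec)
    expect_equal(unname(fit$model$coefficients),
                 drop(ols_oracle(X, design$y)), tolerance = 1e-8)
  }
})

test_that("published flavonoid model statistics are reproduced from the raw runs", {
  fx <- lassi_fixtures()
  fit <- fit_scheffe(fx$design, "total_flavonoid_content", fx$spec)
  # printed: mean 15.38 +/- 0.30 (CV 1.99 implies sd ~0.31), R2 0.9960
  expect_equal(fit$stats$grand_mean, 15.38, tolerance = 0.05)
  expect_equal(fit$stats$root_mse, 0.31, tolerance = 0.05)
  expect_gt(fit$stats$r2, 0.98)
  expect_equal(fit$stats$cv_percent,
               100 * fit$stats$root_mse / fit$stats$grand_mean,
               tolerance = 1e-9)
  expect_lte(fit$stats$adjusted_r2, fit$stats$r2)
  # replicated runs exist, so lack of fit is decomposable
  expect_true(is.finite(fit$stats$lack_of_fit_f))
})

test_that("fit statistics are invariant to run order and flag degenerate fits", {
  fx <- lassi_fixtures()
  set.seed(11)
  perm <- sample(nrow(fx$design))
  f1 <- fit_scheffe(fx$design, "dpph", fx$spec)
  f2 <- fit_scheffe(fx$design[perm, ], "dpph", fx$spec)
  for (field in c("r2", "adjusted_r2", "predicted_r2", "cv_percent",
                  "adequate_precision", "model_f", "grand_mean", "root_mse"))
    expect_equal(f1$stats[[field]], f2$stats[[field]], tolerance = 1e-9)

  const <- fx$design
  const$flat <- 4.2
  expect_warning(fc <- fit_scheffe(const, "flat", fx$spec),
                 "constant response")
  expect_equal(fc$stats$r2, 0)
  expect_equal(unname(fc$model$coefficients),
               c(4.2, 4.2, 4.2, 0, 0, 0, 0), tolerance = 1e-8)
})

test_that("under-determined and rank-deficient designs raise errors", {
  fx <- lassi_fixtures()
  small <- fx$design[1:5, ]
  expect_error(fit_scheffe(small, "dpph", fx$spec), "at least 7 runs")
  dup <- fx$design[rep(1, 8), ]   # 8 copies of one run: rank 1
  expect_error(fit_scheffe(dup, "dpph", fx$spec), "rank-deficient")
})

test_that("published models evaluated at the optimum reproduce the predictions", {
  fx <- lassi_fixtures()
  pseudo <- to_pseudo(fx$optimum_amounts, fx$spec)
  pred <- vapply(fx$models, predict_response, numeric(1L), pseudo = pseudo)
  tab <- setNames(fx$optimum$predicted, fx$optimum$response)
  # the five tightest worked examples agree to 0.05% relative error
  for (r in c("color_appearance", "flavor_sweetness",
              "total_flavonoid_content", "ascorbic_acid",
              "total_phenol_content"))
    expect_equal(pred[[r]], tab[[r]], tolerance = 5e-4)
  # the remaining responses still agree to rounding-level error (< 0.15%),
  # except syneresis whose printed prediction is inconsistent with its
  # printed coefficients
  others <- setdiff(names(tab), "syneresis")
  expect_true(all(abs(pred[others] - tab[others]) / tab[others] < 1.5e-3))
})
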