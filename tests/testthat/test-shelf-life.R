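test_that("limit-based shelf life inverts each order law", {
  # log10 plate count 3.07 -> guideline 6.0 at k = 0.1646/day
  expect_equal(shelf_life_to_limit(3.07, 6, 0.1646, 0, "increasing"),
               (6 - 3.07) / 0.1646, tolerance = 1e-12)
  expect_equal(round(shelf_life_to_limit(3.07, 6, 0.1646, 0, "increasing"), 2),
               17.80)
  # half-change limit coincides with the half-life at every order
  expect_equal(shelf_life_to_limit(8, 4, 0.1, 0, "decreasing"),
               half_life(8, 0.1, 0), tolerance = 1e-12)
  expect_equal(shelf_life_to_limit(8, 4, 0.1, 1, "decreasing"),
               log(2) / 0.1, tolerance = 1e-12)
  expect_equal(shelf_life_to_limit(8, 12, 0.1, 0, "increasing"),
               half_life(8, 0.1, 0), tolerance = 1e-12)
  expect_error(shelf_life_to_limit(8, 9, 0.1, 0, "decreasing"),
               "never reaches")
  expect_error(shelf_life_to_limit(8, 7, 0.1, 0, "increasing"),
               "never reaches")
})

test_that("temperature-resolved shelf life matches the cross-module identity", {
  fx <- lassi_fixtures()
  sub <- fx$rates[fx$rates$index_name == "total_plate_count" &
                    fx$rates$order == 0, ]
  ar <- fit_arrhenius(sub$k, sub$temperature_C)
  # at the reference temperature the half-change estimate is c0/(2 k_ref)
  est_ref <- shelf_life_at_temperature(ar, 3.07, ar$t_ref_c, "half_change")
  expect_equal(est_ref$shelf_life_days, half_life(3.07, ar$k_ref, 0),
               tolerance = 1e-12)
  # at 5 degC the smoothed rate reproduces the published 9.33-day figure
  est5 <- shelf_life_at_temperature(ar, 3.07, 5, "half_change",
                                    index_name = "total_plate_count")
  expect_equal(est5$shelf_life_days, 9.33, tolerance = 0.05)
  # warmer storage always shortens predicted life when Ea > 0
  est25 <- shelf_life_at_temperature(ar, 3.07, 25, "half_change")
  expect_lt(est25$shelf_life_days, est5$shelf_life_days)
  # microbial limit criterion
  lim <- shelf_life_at_temperature(ar, 3.07, 5, "limit", limit = 6,
                                   direction = "increasing")
  expect_gt(lim$shelf_life_days, est5$shelf_life_days)
})

test_that("the stability report covers every index-temperature pair", {
  fx <- lassi_fixtures()
  rep <- stability_report(fx$storage, c0 = fx$day0)
  expect_s3_class(rep, "data.frame")
  expect_equal(nrow(rep), 18L)   # 6 indices x 3 temperatures
  expect_false(any(is.na(rep$k0)))
  tm <- attr(rep, "temperature_models")
  expect_equal(nrow(tm), 6L)
  expect_true(all(tm$delta_S < 0))
  # zero-order rates rise (and half-lives fall) with temperature for every
  # index; the per-series selected order can differ, so compare on a
  # common order
  for (idx in unique(rep$index)) {
    sub <- rep[rep$index == idx, ]
    sub <- sub[order(sub$temperature_C), ]
    expect_false(is.unsorted(sub$k0), info = idx)
    c0_idx <- if (idx %in% names(fx$day0)) fx$day0[[idx]]
              else fx$storage[[paste0(idx, "@5")]]$values[1L]
    expect_false(is.unsorted(rev(c0_idx / (2 * sub$k0))), info = idx)
  }
})

test_that("the published rate table itself is monotone in temperature", {
  fx <- lassi_fixtures()
  sub0 <- fx$rates[fx$rates$order == 0, ]
  for (idx in unique(sub0$index_name)) {
    s <- sub0[sub0$index_name == idx, ]
    s <- s[order(s$temperature_C), ]
    expect_false(is.unsorted(s$k), info = idx)
    expect_false(is.unsorted(rev(s$t_half)), info = idx)
  }
})

test_that("a zero-noise synthetic study reproduces generator truth in the report", {
  sims <- c(simulate_storage(order = 0, c0 = 10, k_ref = 0.2, Ea = 1.5e4,
                             t_ref = 15, index_name = "alpha", seed = 1),
            simulate_storage(order = 0, c0 = 5, k_ref = 0.05, Ea = 1.2e4,
                             t_ref = 15, index_name = "beta", seed = 2))
  rep <- stability_report(sims)
  expect_equal(nrow(rep), 6L)
  expect_true(all(rep$selected_order == 0))
  expect_equal(rep$r2_0, rep(1, 6), tolerance = 1e-10)
  k_true <- c(attr(sims[1:3], "k_true"))
  tm <- attr(rep, "temperature_models")
  expect_equal(tm$Ea[tm$index == "alpha"], 1.5e4, tolerance = 1e-6)
  expect_equal(tm$Ea[tm$index == "beta"], 1.2e4, tolerance = 1e-6)
})

test_that("report files are byte-identical across repeated writes", {
  fx <- lassi_fixtures()
  rep <- stability_report(fx$storage, c0 = fx$day0)
  p1 <- file.path(tempdir(), "rep1.csv")
  p2 <- file.path(tempdir(), "rep2.csv")
  write_report(rep, p1)
  write_report(rep, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(tools::md5sum(p1)[[1]], tools::md5sum(p2)[[1]])
  t1 <- file.path(tempdir(), "rep1.txt")
  write_report(rep, t1, format = "text")
  expect_true(any(grepl("Temperature models:", readLines(t1))))
})
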