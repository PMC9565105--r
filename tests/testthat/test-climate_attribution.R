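test_that("climate model recovers exact coefficients and matches lm", {
  set.seed(21)
  temp <- 2 + rnorm(21, sd = 0.5)
  precip <- 600 + rnorm(21, sd = 50)
  ndvi <- 0.02 * temp + 1e-4 * precip + 0.1
  fit <- fit_climate_model(ndvi, temp, precip)
  expect_equal(fit$a, 0.02, tolerance = 1e-8)
  expect_equal(fit$b, 1e-4, tolerance = 1e-8)
  expect_equal(fit$c, 0.1, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_false(fit$collinearity_flag)

  # constant NDVI: a = b = 0, c = the constant
  fit0 <- fit_climate_model(rep(0.5, 21), temp, precip)
  expect_equal(c(fit0$a, fit0$b, fit0$c), c(0, 0, 0.5), tolerance = 1e-10)

  # random inputs vs the normal-equations oracle
  for (k in 1:20) {
    y <- runif(21); tt <- rnorm(21); pp <- rnorm(21)
    got <- fit_climate_model(y, tt, pp)
    want <- unname(coef(lm(y ~ tt + pp)))
    expect_equal(c(got$c, got$a, got$b), want, tolerance = 1e-10)
    # residuals of an OLS fit with intercept average to zero
    expect_lt(abs(mean(got$residuals)), 1e-10)
    expect_equal(got$residuals, y - got$predicted, tolerance = 1e-12)
  }
  expect_error(fit_climate_model(runif(3), rnorm(3), rnorm(3)), "at least 4")
})

test_that("collinear and constant climate designs are flagged, not fatal", {
  y <- runif(21)
  tt <- 1:21
  fitc <- fit_climate_model(y, tt, 2 * tt + 3) # T, P collinear
  expect_true(fitc$collinearity_flag)
  # predictions still the least-squares projection
  expect_lt(max(abs(fitc$predicted - fitted(lm(y ~ tt)))), 1e-8)

  fit0 <- fit_climate_model(y, rep(2, 21), rep(600, 21))
  expect_true(fit0$collinearity_flag)
  expect_equal(c(fit0$a, fit0$b), c(0, 0))
  expect_equal(fit0$c, mean(y))
})

test_that("six-condition contribution scheme matches the attribution table", {
  # same-sign triples split proportionally
  r <- contribution_rates(0.004, 0.003, 0.001)
  expect_equal(r$cc_pct, 75)
  expect_equal(r$ha_pct, 25)
  expect_identical(r$condition, "proportional_greening")

  cases <- data.frame(
    obs = c(0.004, 0.004, -0.004, -0.004, -0.004, 0.004),
    pre = c(0.005, -0.001, -0.002, -0.005, 0.002, 0.003),
    res = c(-0.001, 0.005, -0.002, 0.001, -0.006, 0.001),
    cc = c(100, 0, 50, 100, 0, 75),
    ha = c(0, 100, 50, 0, 100, 25))
  got <- contribution_rates(cases$obs, cases$pre, cases$res)
  expect_equal(got$cc_pct, cases$cc)
  expect_equal(got$ha_pct, cases$ha)
  # conservation holds exactly in every condition
  expect_true(all(got$cc_pct + got$ha_pct == 100))

  # near-zero observed trend is undefined
  u <- contribution_rates(0, 1e-9, -1e-9)
  expect_identical(u$condition, "undefined_stable")
  expect_true(is.na(u$cc_pct) && is.na(u$ha_pct))

  expect_error(contribution_rates(0.004, 0.001, 0.001), "inconsistent")
})

test_that("same-sign contributions are automatically shares in [0, 100]", {
  set.seed(31)
  obs <- runif(500, -0.01, 0.01)
  pre <- obs * runif(500) # same sign, |pre| <= |obs|
  got <- contribution_rates(obs, pre)
  def <- !is.na(got$cc_pct)
  expect_true(all(got$cc_pct[def] >= 0 & got$cc_pct[def] <= 100))
  expect_true(all(got$cc_pct[def] + got$ha_pct[def] == 100))
})

test_that("attribution map decomposes slopes exactly and honors pure limits", {
  # pure climate: no human trend, no observation noise -> CC = 100 everywhere
  sc <- generate_scenario(scenario_config(nrow = 6, ncol = 6,
                                          human_rate = 0, noise_sd = 0))
  am <- attribute_map(sc$ndvi, sc$temp, sc$precip)
  def <- !is.na(am$cc_pct)
  expect_true(all(am$cc_pct[def] == 100))
  expect_true(all(am$ha_pct[def] == 0))
  expect_equal(am$summary$mean_cc, 100)

  # pure human: constant climate, human trend only -> CC = 0 everywhere
  sc2 <- generate_scenario(scenario_config(nrow = 6, ncol = 6,
                                           temp_trend = 0, precip_trend = 0,
                                           temp_sd = 0, precip_sd = 0,
                                           human_rate = 0.002, noise_sd = 0))
  am2 <- attribute_map(sc2$ndvi, sc2$temp, sc2$precip)
  expect_true(all(am2$cc_pct == 0))
  expect_true(all(am2$ha_pct == 100))

  # decomposition identity on a noisy scenario
  sc3 <- generate_scenario(scenario_config(nrow = 8, ncol = 8, seed = 5))
  am3 <- attribute_map(sc3$ndvi, sc3$temp, sc3$precip)
  expect_lt(max(abs(am3$slope_obs - am3$slope_pre - am3$slope_res)), 1e-10)
  def3 <- !is.na(am3$cc_pct)
  expect_true(all(am3$cc_pct[def3] + am3$ha_pct[def3] == 100))
})

test_that("attribution map reports zonal human-activity summaries", {
  sc <- generate_scenario(scenario_config(nrow = 4, ncol = 6, seed = 9))
  zones <- make_zones(4, 6)
  am <- attribute_map(sc$ndvi, sc$temp, sc$precip, zones = zones)
  expect_true(all(c("zonal_mean_ha", "zonal_ha_bins") %in%
                  names(am$summary)))
  bins <- am$summary$zonal_ha_bins
  expect_equal(nrow(bins), 2 * 5) # two zones x five 20-point bins
  for (z in unique(bins$zone)) {
    zn <- bins[bins$zone == z, ]
    expect_equal(sum(zn$count),
                 am$summary$zonal_mean_ha$n[am$summary$zonal_mean_ha$zone == z])
  }
})
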