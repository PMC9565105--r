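test_that("rescaled range follows the hand-worked example", {
  # series 1,2,3,4 at r = 2: each group has X = (-0.5, 0), R = 0.5,
  # S = 0.5, so R/S = 1 in both groups and RS-bar(2) = 1
  cv <- rs_curve(c(1, 2, 3, 4), window_sizes = 2)
  expect_equal(cv$rs_bar, 1)
  expect_equal(cv$n_groups, 2L)
})

test_that("window grid and remainder handling follow the n/2 rule", {
  x <- rnorm(21)
  cv <- rs_curve(x)
  expect_identical(cv$r, 2:10)
  expect_identical(cv$n_groups[cv$r == 2], 10L) # one trailing point dropped
  expect_error(rs_curve(rep(1, 12)), "usable")
  expect_error(rs_curve(rnorm(3)), "at least 4")
  expect_error(rs_curve(rnorm(20), window_sizes = c(2, 11)), "\\[2, floor")
})

test_that("rs_curve equals the literal independent oracle on short series", {
  set.seed(55)
  for (k in 1:40) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    got <- rs_curve(x)
    want <- rs_oracle(x)
    expect_equal(got$r, want$r)
    expect_equal(got$rs_bar, want$rs_bar, tolerance = 1e-12)
  }
})

test_that("Hurst estimation is affine-invariant", {
  set.seed(66)
  x <- rnorm(64)
  h0 <- hurst_exponent(x)
  h1 <- hurst_exponent(2 * x + 5)
  expect_equal(h1$H, h0$H, tolerance = 1e-12)
  expect_equal(h1$rs_points$rs_bar, h0$rs_points$rs_bar, tolerance = 1e-12)
})

test_that("mean Hurst estimates order the generator's H values", {
  est <- function(H) {
    mean(vapply(1:60, function(s) {
      hurst_exponent(generate_fgn(1024, H, seed = 5000 + s),
                     window_sizes = 2^(4:7))$H
    }, 0))
  }
  h3 <- est(0.3); h5 <- est(0.5); h8 <- est(0.8)
  expect_lt(h3, h5)
  expect_lt(h5, h8)
  expect_lt(abs(h8 - 0.8), 0.1)
})

test_that("seven-class persistence labels honor the printed boundaries", {
  expect_identical(classify_h7(0.66), structure("medium_sust",
                                                clamped = FALSE))
  expect_identical(as.vector(classify_h7(0.26)), "medium_anti")
  expect_identical(as.vector(classify_h7(0.97)), "strong_sust")
  expect_identical(
    as.vector(classify_h7(c(0.2, 0.35, 0.5, 0.65, 0.8))),
    c("strong_anti", "medium_anti", "random", "weak_sust", "medium_sust"))
  # partition of (0, 1): exactly one label for any H
  set.seed(8)
  H <- c(runif(200), 0.2, 0.35, 0.5, 0.65, 0.8)
  H <- H[H > 0 & H < 1]
  lab <- classify_h7(H)
  expect_true(all(lab %in% c("strong_anti", "medium_anti", "weak_anti",
                             "random", "weak_sust", "medium_sust",
                             "strong_sust")))
  # out-of-range estimates are clamped and flagged
  cl <- classify_h7(c(-0.1, 1.3))
  expect_identical(as.vector(cl), c("strong_anti", "strong_sust"))
  expect_identical(attr(cl, "clamped"), c(TRUE, TRUE))
  expect_error(classify_h7(NA_real_), "non-finite")
  expect_error(classify_h7(1.2, clamp = FALSE), "outside")
})

test_that("combined trend x persistence labels enumerate 15 cases", {
  expect_identical(combine_trend_persistence(0.003, "medium_sust"),
                   "improvement_medium_sust")
  expect_identical(combine_trend_persistence(-0.002, "weak_sust"),
                   "degradation_weak_sust")
  slopes <- c(-0.002, 0, 0.002)
  classes <- c("medium_anti", "weak_anti", "weak_sust", "medium_sust",
               "strong_sust") # H in (0.2, 1) \ {0.5}
  grid <- expand.grid(s = slopes, h = classes,
                      stringsAsFactors = FALSE)
  labels <- combine_trend_persistence(grid$s, grid$h)
  expect_identical(length(unique(labels)), 15L)
  expect_error(combine_trend_persistence(0.1, "great_sust"), "unknown")
})

test_that("hotspot masks gate on trend, significance and persistence", {
  slope <- matrix(c(-0.004, 0.004, 0.004, 0.0005), 2, 2)
  p <- matrix(c(0.02, 0.02, 0.5, 0.02), 2, 2)
  H <- matrix(c(0.7, 0.4, 0.4, 0.4), 2, 2)
  hot <- extract_hotspots(slope, p, H)
  expect_identical(hot$degradation_sustained,
                   matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_identical(hot$improvement_unsustained,
                   matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  expect_false(any(hot$degradation_sustained & hot$improvement_unsustained))
  # NA-safe
  slope[1, 1] <- NA
  hot2 <- extract_hotspots(slope, p, H)
  expect_false(hot2$degradation_sustained[1, 1])
})

test_that("hurst_map summarises per-pixel persistence", {
  sc <- generate_scenario(scenario_config(nrow = 5, ncol = 5, seed = 12))
  hm <- hurst_map(sc$ndvi)
  expect_equal(dim(hm$H), c(5, 5))
  expect_true(all(is.finite(hm$H)))
  expect_equal(sum(hm$summary$class_shares$fraction), 1, tolerance = 1e-12)
  expect_true(hm$summary$min_H <= hm$summary$mean_H &
              hm$summary$mean_H <= hm$summary$max_H)
})
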