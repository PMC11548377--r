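test_that("OLS recovers exact lines and degrades gracefully", {
  x <- 1:5
  fit <- linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- linear_fit(x, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
  expect_error(linear_fit(1:2, 1:2), "insufficient")
})

test_that("OLS slope lands within 3 standard errors of the truth", {
  set.seed(2024)
  x <- runif(200, 0, 1)
  y <- 0.4 - 2.5 * x + rnorm(200, 0, 0.3)
  fit <- linear_fit(x, y)
  expect_lt(abs(fit$slope - (-2.5)), 3 * fit$slope_se)
  expect_lt(fit$p_value, 1e-6)
})

test_that("OLS is scale-equivariant and R^2 equals squared correlation", {
  set.seed(5)
  x <- rnorm(50); y <- 1 + 0.5 * x + rnorm(50, 0, 0.4)
  f1 <- linear_fit(x, y)
  f2 <- linear_fit(10 * x, y)
  expect_equal(f2$slope, f1$slope / 10, tolerance = 1e-10)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-10)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-10)
  expect_equal(f1$r_squared, cor(x, y)^2, tolerance = 1e-10)
})

test_that("the depth/transparency ratio and its limitation flag behave", {
  expect_equal(zm_zsd_ratio(2.0, 0.5), 4.0)
  expect_equal(zm_zsd_ratio(1.3, 1.3), 1.0)
  # summer field check: 1.96 m over a 35 cm Secchi depth
  expect_equal(zm_zsd_ratio(1.96, 0.35), 5.6)
  expect_error(zm_zsd_ratio(2, 0), "positive")
  expect_true(flag_light_limitation(5.2))
  expect_false(flag_light_limitation(5.17))  # strict at the boundary
  expect_false(flag_light_limitation(1.0))
  r <- c(1, 5.17, 5.18, 9)
  expect_equal(flag_light_limitation(r), c(FALSE, FALSE, TRUE, TRUE))
  # monotone in the ratio
  expect_true(all(diff(flag_light_limitation(seq(0, 10, 0.5))) >= 0))
})

test_that("seasonal comparison letters separate what differs and only that", {
  set.seed(77)
  same <- data.frame(season = rep(c("spring", "summer"), each = 40),
                     TP = rnorm(80, 0.05, 0.01))
  s1 <- seasonal_compare(same, "TP")
  expect_true(s1$letters[1] == s1$letters[2])  # same distribution, one letter
  far <- data.frame(season = rep(c("spring", "summer"), each = 20),
                    TP = c(rnorm(20, 0.03, 0.005), rnorm(20, 0.13, 0.005)))
  s2 <- seasonal_compare(far, "TP")
  expect_false(grepl(s2$letters[1], s2$letters[2], fixed = TRUE))
  one <- data.frame(season = rep("spring", 5), TP = rnorm(5, 0.05, 0.01))
  s3 <- seasonal_compare(one, "TP")
  expect_equal(nrow(s3), 1)
  expect_equal(s3$n, 5L)
  # a season with < 2 observations is summarised without a letter
  lone <- data.frame(season = c(rep("spring", 10), rep("summer", 10),
                                "autumn"),
                     TP = c(rnorm(10, 0.03, 0.005), rnorm(10, 0.13, 0.005),
                            0.07))
  s4 <- seasonal_compare(lone, "TP")
  expect_true(is.na(s4$letters[s4$season == "autumn"]))
  expect_false(is.na(s4$letters[s4$season == "spring"]))
})

test_that("a three-level gradient yields an a / ab / b letter chain", {
  set.seed(11)
  n <- 10
  # tight extremes, a diffuse middle group: extremes separate, the middle
  # cannot be told from either neighbour
  d <- data.frame(
    season = rep(c("spring", "summer", "autumn"), each = n),
    TP = c(rnorm(n, 0.00, 0.001), rnorm(n, 0.50, 1.50),
           rnorm(n, 1.00, 0.001)))
  s <- seasonal_compare(d, "TP")
  sp <- s$letters[s$season == "spring"]
  su <- s$letters[s$season == "summer"]
  au <- s$letters[s$season == "autumn"]
  # extremes differ; the middle shares a letter with at least one neighbour
  expect_false(any(strsplit(sp, "")[[1]] %in% strsplit(au, "")[[1]]))
  expect_true(any(strsplit(su, "")[[1]] %in%
                  c(strsplit(sp, "")[[1]], strsplit(au, "")[[1]])))
})

test_that("slope confidence intervals cover the truth at the nominal rate", {
  covered <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    sim <- generate_env_series(n_dates = 40, a = 0.65, b = -5, sigma = 0.08,
                               seed = 1000 + r)
    fit <- linear_fit(sim$env$TP, sim$coverage$sav_coverage)
    half <- qt(0.975, fit$n - 2) * fit$slope_se
    if (abs(fit$slope - sim$truth$b) <= half) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.9)
})
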