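# The three truncation-handling strategies and SD recovery.

make_truncated <- function(seed = 20131207, n = 100) {
  sim <- simulate_from_dating(verburg_equation(), n_per_value = n, seed = seed)
  truncate_ga(sim)
}

test_that("with no truncation and no augmentation the approaches collapse to the direct fit", {
  eq <- verburg_equation()
  obs <- simulate_from_dating(eq, crl_grid = seq(5, 110, by = 3),
                              n_per_value = 25, seed = 31)
  direct <- fit_dating_model(obs)
  a1 <- run_approach1(obs, approach1_config(augment_days = integer(0),
                                            restrict_crl = c(1, 200)),
                      plausible_crl = NULL)
  expect_equal(a1$mean$powers, direct$mean$powers)
  expect_equal(a1$mean$coefficients, direct$mean$coefficients, tolerance = 1e-10)
  expect_equal(a1$mean$intercept, direct$mean$intercept, tolerance = 1e-10)
  expect_equal(a1$sd$powers, direct$sd$powers)
  expect_equal(a1$sd$intercept, direct$sd$intercept, tolerance = 1e-10)
  a2 <- run_approach2(obs, approach2_config(augment_days_low = integer(0),
                                            augment_days_high = integer(0)),
                      plausible_crl = NULL)
  expect_equal(a2$mean$powers, direct$mean$powers)
  expect_equal(a2$mean$coefficients, direct$mean$coefficients, tolerance = 1e-10)
})

test_that("axis interchange inverts exact lognormal centile coordinates", {
  # coordinates generated exactly from a known dating model: the centile
  # regressions and the recovered SD must reproduce that model
  eq <- dating_equation(b0 = 1.4653, b1 = 0.001737, b2 = 0.2313, sigma = 0.0459)
  crl <- seq(8, 110, by = 1)
  g50 <- as.numeric(predict_centile(eq, crl, 0.5))
  g3 <- as.numeric(predict_centile(eq, crl, 0.03))
  g97 <- as.numeric(predict_centile(eq, crl, 0.97))
  med_fit <- fit_fp_mean(crl, g50, outcome_log = TRUE, covariate_name = "crl_mm")
  grid <- seq(10, 100, by = 5)
  expect_lt(max(abs(exp(predict(med_fit, grid)) -
                    as.numeric(predict_centile(eq, grid, 0.5)))) * 7, 0.05)
  sd_fit <- recover_sd_from_centiles(crl, g3, g50, g97, covariate_name = "crl_mm")
  expect_equal(predict(sd_fit, grid), rep(0.0459, length(grid)),
               tolerance = 1e-8)
})

test_that("SD recovery averages the two log-scale half-spreads", {
  x <- seq(10, 90, by = 5)
  c50 <- exp(1.4 + 0.002 * x + 0.23 * log(x))
  K <- qnorm(0.97)
  sigma <- 0.0459
  c3 <- c50 * exp(-K * sigma)
  c97 <- c50 * exp(K * sigma)
  m <- recover_sd_from_centiles(x, c3, c50, c97, K = K)
  expect_equal(predict(m, x), rep(sigma, length(x)), tolerance = 1e-10)
  expect_error(recover_sd_from_centiles(x, c50, c3, c97),
               class = "crldating_invalid_centiles")
})

test_that("fitted dating models have strictly increasing medians over 10-100 mm", {
  obs <- make_truncated(seed = 14)
  grid <- seq(10, 100, by = 1)
  a1 <- run_approach1(obs, seed = 15)
  a2 <- run_approach2(obs, seed = 16)
  a3 <- run_approach3(obs)
  for (m in list(a1, a2, a3))
    expect_true(all(diff(as.numeric(predict_centile(m, grid, 0.5))) > 0))
})

test_that("approach 2 keeps both augmentation blocks and the observed rows", {
  obs <- make_truncated(seed = 21, n = 40)
  a2 <- run_approach2(obs, approach2_config(n_per_day = 40), seed = 22)
  d <- attr(a2, "approach")$data
  expect_equal(nrow(d), nrow(obs) + 40 * (14 + 22))
  expect_setequal(unique(d$source),
                  c("observed", "simulated_low", "simulated_high"))
})

test_that("approach 1 recovers a user-chosen generating equation mid-range", {
  gen <- dating_equation(b0 = 1.40, b1 = 0.0018, b2 = 0.24, sigma = 0.03)
  obs <- truncate_ga(simulate_from_dating(gen, n_per_value = 100, seed = 51))
  a1 <- run_approach1(obs, seed = 52)
  truth <- as.numeric(predict_centile(gen, 40, 0.5))
  got <- as.numeric(predict_centile(a1, 40, 0.5))
  expect_lt(abs(got - truth) * 7, 0.35)  # ~3 Monte-Carlo SEs in days
})

test_that("approach 1 demands data inside the restriction window", {
  obs <- make_truncated(seed = 61, n = 20)
  expect_error(run_approach1(obs, approach1_config(augment_days = integer(0),
                                                   restrict_crl = c(150, 160))),
               class = "crldating_insufficient_data")
})

test_that("the sensitivity table reduces to a single approach-1 run", {
  obs <- make_truncated(seed = 71, n = 60)
  cfg <- approach1_config(n_per_day = 60, sensitivity_cutoffs = 20)
  tab <- sensitivity_lower_cutoff(obs, cfg, verburg_equation(), seed = 72)
  expect_equal(nrow(tab), 1L)
  model <- run_approach1(obs, cfg, seed = 72)
  cmp <- compare_to_reference(model, verburg_equation(), seq(20, 100, 5))
  s <- agreement_summary(cmp, c(20, 100), "median")
  expect_equal(tab$max_abs_diff_days, s$max_abs_diff_days, tolerance = 1e-12)
  expect_equal(tab$mean_diff_days, s$mean_diff_days, tolerance = 1e-12)
})

test_that("approach-3 configurations are validated", {
  expect_error(approach3_config(ga_eval_days = c(60, 60.5)),
               class = "crldating_invalid_input")
  expect_error(approach3_config(levels = c(0.1, 0.4, 0.9)),
               class = "crldating_invalid_input")
})
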