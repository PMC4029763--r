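# Fractional-polynomial fitting and centile evaluation.

test_that("fixed-power FP fits equal the normal-equations OLS solution", {
  d <- fixture_xy()
  for (pw in list(1, 0, -2, c(0, 1), c(-0.5, 2), c(2, 2), c(0, 0))) {
    m <- fit_fp_mean(d$x, d$y, powers = pw)
    oracle <- ols_oracle(d$x, d$y, pw)
    expect_equal(m$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(m$coefficients, unname(oracle[-1]), tolerance = 1e-10)
  }
})

test_that("exact linear data is reproduced to machine precision", {
  x <- 1:50
  y <- 2 + 3 * x
  m <- fit_fp_mean(x, y)
  expect_equal(predict(m, x), y, tolerance = 1e-8)
})

test_that("repeated powers expand to the (x^p, x^p ln x) basis", {
  m <- fp_model(c(2, 2), c(1.5, -0.25), 3)
  x <- c(1.3, 4, 9)
  expect_equal(predict(m, x), 3 + 1.5 * x^2 - 0.25 * x^2 * log(x))
  m0 <- fp_model(c(0, 0), c(2, 1), 0)
  expect_equal(predict(m0, x), 2 * log(x) + log(x)^2)
})

test_that("invalid FP specifications are rejected", {
  expect_error(fp_model(c(0, 1, 2), c(1, 1, 1), 0), class = "crldating_invalid_input")
  expect_error(fp_model(0.25, 1, 0), class = "crldating_invalid_input")
  expect_error(fit_fp_mean(c(-1, 1:19), rnorm(20)), class = "crldating_invalid_input")
  expect_error(fit_fp_mean(1:5, 1:5), class = "crldating_invalid_input")
  expect_error(fit_fp_mean(rep(2, 20), rnorm(20)), class = "crldating_degenerate_design")
  expect_error(predict(fp_model(1, 1, 0), c(1, 0)), class = "crldating_invalid_input")
})

test_that("outcome_log fits operate on the natural-log scale", {
  x <- seq(5, 100, length.out = 40)
  y <- exp(1.4 + 0.002 * x + 0.23 * log(x))
  m <- fit_fp_mean(x, y, outcome_log = TRUE, powers = c(0, 1))
  expect_true(m$outcome_log)
  expect_equal(predict(m, x), log(y), tolerance = 1e-8)
  expect_error(fit_fp_mean(x, c(-1, y[-1]), outcome_log = TRUE),
               class = "crldating_invalid_input")
})

test_that("SD fitting recovers homoscedastic and heteroscedastic spreads", {
  set.seed(7)
  # constant spread: fitted curve close to sigma at all x
  x <- rep(seq(5, 50, by = 5), each = 400)
  r <- rnorm(length(x), 0, 0.04)
  s <- fit_fp_sd(x, r)
  expect_true(all(abs(predict(s, seq(5, 50, by = 5)) - 0.04) < 0.004))
  # linear spread: recovered slope within 3 standard errors of truth
  sd_true <- 0.02 + 0.001 * x
  r2 <- rnorm(length(x), 0, sd_true)
  s2 <- fit_fp_sd(x, r2)
  fitted_sd <- predict(s2, c(10, 40))
  slope <- diff(fitted_sd) / 30
  # se of a regression slope on |r|*sqrt(pi/2): estimated from theory below
  se <- sqrt((pi / 2 - 1) * mean(sd_true^2) / sum((x - mean(x))^2))
  expect_lt(abs(slope - 0.001), 3 * se)
})

test_that("mean/SD pairs with a non-positive SD curve are rejected", {
  mean <- fp_model(1, 0.01, 2, outcome_log = TRUE, covariate_name = "crl_mm")
  bad_sd <- fp_model(1, -0.01, 0.1, covariate_name = "crl_mm",
                     fit_range = c(1, 100))
  expect_error(mean_sd_model(mean, bad_sd, "ga_weeks"),
               class = "crldating_invalid_sd")
  other <- fp_model(1, 0.01, 2, covariate_name = "ga_weeks")
  expect_error(mean_sd_model(mean, other, "ga_weeks"),
               class = "crldating_invalid_input")
})

test_that("centiles are monotone in K and log-symmetric about the median", {
  set.seed(11)
  for (i in 1:10) {
    mean <- fp_model(sample(c(-1, -0.5, 0, 0.5, 1), 1), runif(1, 0.001, 0.01),
                     runif(1, 1, 2), outcome_log = TRUE, covariate_name = "crl_mm")
    sd <- fp_model(numeric(0), numeric(0), runif(1, 0.01, 0.1), covariate_name = "crl_mm")
    m <- mean_sd_model(mean, sd, "ga_weeks", class = "dating_model")
    x <- runif(5, 5, 100)
    ks <- sort(runif(4, -3, 3))
    cent <- sapply(ks, function(k)
      as.numeric(predict_centile(m, x, spec = centile_spec(0.5, K = k))))
    expect_true(all(apply(cent, 1, diff) > 0))
    c3 <- predict_centile(m, x, 0.03)
    c50 <- predict_centile(m, x, 0.5)
    c97 <- predict_centile(m, x, 0.97)
    expect_equal(log(c97) - log(c50), log(c50) - log(c3), tolerance = 1e-12)
  }
})

test_that("the median centile equals exp(mean) for log-scale models", {
  eq <- verburg_equation()
  x <- c(5, 23, 50, 88)
  expect_equal(as.numeric(predict_centile(eq, x, 0.5)),
               exp(predict(eq$mean, x)), tolerance = 1e-12)
})

test_that("z scores recover the standardised residual distribution", {
  eq <- verburg_equation()
  # observations on the median curve score zero; on the 97th, K exactly
  crl <- seq(10, 100, by = 10)
  med <- observation_set(crl, as.numeric(predict_centile(eq, crl, 0.5)))
  expect_equal(zscores(eq, med), rep(0, length(crl)), tolerance = 1e-10)
  upper <- observation_set(crl, as.numeric(predict_centile(eq, crl, 0.97)))
  expect_equal(zscores(eq, upper), rep(qnorm(0.97), length(crl)),
               tolerance = 1e-10)
  # data simulated from the model: mean ~ 0, sd ~ 1
  obs <- simulate_from_dating(eq, crl_grid = seq(5, 105, by = 1),
                              n_per_value = 100, seed = 99)
  z <- zscores(eq, obs)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(sd(z) - 1), 0.03)
})

test_that("centile_spec validates its level and defaults K to qnorm", {
  s <- centile_spec(0.97)
  expect_equal(s$K, qnorm(0.97))
  expect_equal(centile_spec(0.5)$K, 0)
  expect_equal(centile_spec(0.03)$K, -centile_spec(0.97)$K)
  expect_error(centile_spec(1.2), class = "crldating_invalid_input")
})

test_that("refitting data simulated from a known model recovers its medians", {
  eq <- dating_equation(b0 = 1.3, b1 = 0.002, b2 = 0.25, sigma = 0.04)
  obs <- simulate_from_dating(eq, crl_grid = seq(5, 110, by = 1),
                              n_per_value = 100, seed = 5)
  fit <- fit_dating_model(obs)
  grid <- seq(10, 100, by = 5)
  truth <- as.numeric(predict_centile(eq, grid, 0.5))
  got <- as.numeric(predict_centile(fit, grid, 0.5))
  # 3 Monte-Carlo standard errors of a local median with ~100 obs per mm
  mc_se <- truth * 0.04 / sqrt(100 * 10)
  expect_true(all(abs(got - truth) < 3 * mc_se + 0.01))
})
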