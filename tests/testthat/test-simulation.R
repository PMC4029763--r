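# Simulation engine: dating draws, size-model augmentation draws, truncation.

test_that("the default dating simulation has the expected bookkeeping", {
  obs <- simulate_from_dating(verburg_equation(), seed = 3)
  expect_equal(nrow(obs), 10600L)
  expect_true(all(obs$source == "observed"))
  expect_equal(sort(unique(obs$crl_mm)), as.numeric(5:110))
  expect_true(all(table(obs$crl_mm) == 100))
})

test_that("degenerate noise reproduces the median curve exactly", {
  eq <- verburg_equation()
  eq$sd$intercept <- 0  # sigma = 0: every draw lands on the median
  obs <- simulate_from_dating(eq, crl_grid = c(10, 50, 90), n_per_value = 5,
                              seed = 1)
  expect_equal(obs$ga_weeks, exp(predict(eq$mean, obs$crl_mm)), tolerance = 1e-12)
})

test_that("draws match the analytic log-scale moments", {
  obs <- simulate_from_dating(verburg_equation(), crl_grid = 50,
                              n_per_value = 100, seed = 8)
  analytic <- 1.4653 + 0.001737 * 50 + 0.2313 * log(50)
  expect_equal(analytic, 2.4570, tolerance = 1e-4)
  expect_lt(abs(mean(log(obs$ga_weeks)) - analytic), 3 * 0.04590 / sqrt(100))
})

test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  a <- simulate_from_dating(verburg_equation(), crl_grid = 5:20,
                            n_per_value = 10, seed = 123)
  b <- simulate_from_dating(verburg_equation(), crl_grid = 5:20,
                            n_per_value = 10, seed = 123)
  expect_identical(a$ga_weeks, b$ga_weeks)
  c <- simulate_from_dating(verburg_equation(), crl_grid = 5:20,
                            n_per_value = 10, seed = 124)
  expect_false(identical(a$ga_weeks, c$ga_weeks))
  set.seed(77); before <- .Random.seed
  simulate_from_dating(verburg_equation(), crl_grid = 5:10, n_per_value = 2,
                       seed = 9)
  expect_identical(before, .Random.seed)
})

test_that("size-model draws are tagged by truncation side and counted", {
  sim <- simulate_from_dating(verburg_equation(), seed = 2)
  tr <- truncate_ga(sim)
  size <- fit_size_model(tr, plausible_range = c(7, 17))
  low <- simulate_from_size(size, 49:62, 100, seed = 4)
  expect_equal(nrow(low), 1400L)
  expect_true(all(low$source == "simulated_low"))
  expect_true(all(low$ga_weeks < 9))
  high <- simulate_from_size(size, 98:119, 100, seed = 4)
  expect_equal(nrow(high), 2200L)
  expect_true(all(high$source == "simulated_high"))
  expect_true(all(high$crl_mm > 0))
  # spread at a fixed day close to the size model's own SD
  day <- simulate_from_size(size, rep(105, 1), 4000, seed = 6)
  expect_lt(abs(sd(day$crl_mm) - predict(size$sd, 15)) / predict(size$sd, 15),
            0.1)
})

test_that("GA truncation is half-open, idempotent and order-preserving", {
  obs <- observation_set(crl_mm = c(10, 20, 30, 40, 50),
                         ga_weeks = c(8.999, 9, 11.5, 13.999, 14))
  tr <- truncate_ga(obs, truncation_window(9, 14))
  expect_equal(tr$ga_weeks, c(9, 11.5, 13.999))  # 9 kept, 14 dropped
  expect_equal(as.data.frame(truncate_ga(tr, truncation_window(9, 14)))[
    , 1:3], as.data.frame(tr)[, 1:3])
  all_pass <- truncate_ga(obs, truncation_window(0, Inf))
  expect_equal(all_pass$ga_weeks, obs$ga_weeks)
})

test_that("truncation matches an independent row-by-row filter", {
  obs <- simulate_from_dating(verburg_equation(), crl_grid = seq(5, 110, 5),
                              n_per_value = 40, seed = 0)
  tr <- truncate_ga(obs, truncation_window(9, 14))
  manual <- 0L
  for (i in seq_len(nrow(obs)))
    if (obs$ga_weeks[i] >= 9 && obs$ga_weeks[i] < 14) manual <- manual + 1L
  expect_equal(nrow(tr), manual)
  expect_true(nrow(tr) <= nrow(obs))
})

test_that("observation sets validate their inputs", {
  expect_error(observation_set(c(1, -2), c(9, 10)), class = "crldating_invalid_input")
  expect_error(observation_set(1:2, c(9, -1)), class = "crldating_invalid_input")
  expect_error(observation_set(1:2, c(9, 10), "whatever"),
               class = "crldating_invalid_input")
  expect_error(simulate_from_dating(verburg_equation(), crl_grid = c(5, -1)),
               class = "crldating_invalid_input")
  expect_error(simulate_from_dating(verburg_equation(), n_per_value = 0),
               class = "crldating_invalid_input")
  expect_error(truncation_window(14, 9), class = "crldating_invalid_input")
})
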