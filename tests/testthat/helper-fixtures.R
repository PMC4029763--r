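# Shared fixtures: everything is generated in code at test time.

# independent normal-equations OLS oracle for a fixed FP basis
ols_oracle <- function(x, y, powers) {
  one <- function(p) if (p == 0) log(x) else x^p
  X <- if (length(powers) == 0) cbind(rep(1, length(x)))
  else if (length(powers) == 1) cbind(1, one(powers[1]))
  else if (powers[1] == powers[2]) cbind(1, one(powers[1]), one(powers[1]) * log(x))
  else cbind(1, one(powers[1]), one(powers[2]))
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# small deterministic covariate/outcome fixture
fixture_xy <- function(n = 20, seed = 42) {
  set.seed(seed)
  x <- seq(2, 60, length.out = n)
  y <- 1.2 + 0.3 * log(x) + 0.002 * x + rnorm(n, 0, 0.05)
  list(x = x, y = y)
}

# cached full-scale study (10,600 rows, default configuration) shared by the
# acceptance tests; computed once per test run
study_cache <- new.env()
get_study <- function(seed = 20131207) {
  key <- paste0("s", seed)
  if (is.null(study_cache[[key]]))
    study_cache[[key]] <- run_truncation_study(seed = seed, verbose = FALSE)
  study_cache[[key]]
}
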