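# Mean-and-SD centile models: a pair of FP curves for the conditional mean
# and SD, from which any centile follows as mean + K * SD on the modelled
# scale (exponentiated when the outcome is modelled on the log scale).

#' Centile specification
#'
#' @param level Probability in (0, 1).
#' @param K Normal equivalent deviate (z score) for the level; defaults to the
#'   exact standard-normal quantile `qnorm(level)`. Published charts often
#'   round this (1.88 for the 97th centile); pass `K` explicitly to reproduce
#'   a rounded convention.
#' @return A list with elements `level` and `K`, class `centile_spec`.
#' @export
centile_spec <- function(level, K = stats::qnorm(level)) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    cd_stop("level must be a probability in (0, 1)", "invalid_input")
  structure(list(level = level, K = K), class = "centile_spec")
}

#' Combine mean and SD FP models into a centile model
#'
#' @param mean An [fp_model()] for the conditional mean (on the modelled
#'   scale: natural log when `mean$outcome_log` is `TRUE`).
#' @param sd An [fp_model()] for the conditional SD on the same modelled
#'   scale; must share the mean model's covariate and be positive over its
#'   fit range.
#' @param outcome_name Label for the outcome (e.g. `"ga_weeks"`).
#' @param class Extra S3 class: `"size_model"` (outcome CRL in mm, covariate
#'   GA in weeks) or `"dating_model"` (outcome GA in weeks on the log scale,
#'   covariate CRL in mm).
#' @return An object of class `mean_sd_model` (plus `class` if given).
#' @export
mean_sd_model <- function(mean, sd, outcome_name = "y", class = NULL) {
  if (!inherits(mean, "fp_model") || !inherits(sd, "fp_model"))
    cd_stop("mean and sd must be fp_model objects", "invalid_input")
  if (!identical(mean$covariate_name, sd$covariate_name))
    cd_stop("mean and sd models must share a covariate", "invalid_input")
  rng <- mean$fit_range %||% sd$fit_range
  if (!is.null(rng)) {
    grid <- seq(rng[1], rng[2], length.out = 101)
    if (any(predict(sd, grid) <= 0))
      cd_stop("SD model is non-positive within the fit range", "invalid_sd")
  }
  structure(list(mean = mean, sd = sd, outcome_name = outcome_name),
            class = c(class, "mean_sd_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mean_sd_model <- function(x, ...) {
  kind <- if (inherits(x, "dating_model")) "Dating model"
          else if (inherits(x, "size_model")) "Size model" else "Mean/SD centile model"
  cat(sprintf("%s: %s as a function of %s\n", kind, x$outcome_name,
              x$mean$covariate_name))
  cat("Mean"); if (x$mean$outcome_log) cat(" (of log outcome)"); cat(":\n")
  print(x$mean)
  cat("SD:\n")
  print(x$sd)
  invisible(x)
}

#' Closed-form lognormal dating equation
#'
#' Builds a dating model from coefficients of
#' `mean of ln(GA) = b0 + b1 * CRL + b2 * ln(CRL)` with a constant SD of
#' ln(GA). GA is in weeks, CRL in mm, and all logarithms natural.
#'
#' @param b0,b1,b2 Coefficients of the mean-of-log-GA equation.
#' @param sigma Constant SD of ln(GA), > 0; alternatively an [fp_model()].
#' @return A `dating_equation`, usable anywhere a `dating_model` is.
#' @export
dating_equation <- function(b0, b1, b2, sigma) {
  if (is.numeric(sigma)) {
    if (length(sigma) != 1L || sigma <= 0)
      cd_stop("sigma must be a single positive number", "invalid_sd")
    sigma <- fp_model(numeric(0), numeric(0), sigma, FALSE, "crl_mm")
  }
  mean <- fp_model(c(0, 1), c(b2, b1), b0, outcome_log = TRUE,
                   covariate_name = "crl_mm")
  m <- mean_sd_model(mean, sigma, outcome_name = "ga_weeks",
                     class = c("dating_equation", "dating_model"))
  m
}

#' The Verburg dating equation
#'
#' The published lognormal ultrasound dating equation used as simulation
#' ground truth: mean of ln(GA) = 1.4653 + 0.001737 CRL + 0.2313 ln(CRL),
#' SD of ln(GA) = 0.04590, for GA in weeks and CRL in mm.
#'
#' @return A [dating_equation()].
#' @export
verburg_equation <- function() {
  dating_equation(b0 = 1.4653, b1 = 0.001737, b2 = 0.2313, sigma = 0.04590)
}

#' Predict a centile from a mean/SD model
#'
#' Computes `mean(x) + K * sd(x)` on the modelled scale and, for log-scale
#' outcomes, exponentiates to the natural scale. `K = 0` (level 0.5) gives the
#' median curve exactly.
#'
#' @param model A [mean_sd_model()].
#' @param x Covariate values, > 0. Values outside the fit range are permitted
#'   (FP models extrapolate) and flagged in the `"extrapolated"` attribute.
#' @param level Centile level in (0, 1); ignored when `spec` is supplied.
#' @param spec A [centile_spec()]; overrides `level`.
#' @return Numeric vector of outcome values on the natural scale, with a
#'   logical attribute `extrapolated` marking values outside the fit range.
#' @export
predict_centile <- function(model, x, level = 0.5, spec = NULL) {
  if (!inherits(model, "mean_sd_model"))
    cd_stop("model must be a mean_sd_model", "invalid_input")
  spec <- spec %||% centile_spec(level)
  mu <- predict(model$mean, x)
  sd <- predict(model$sd, x)
  if (any(sd <= 0))
    cd_stop("predicted SD is non-positive at some covariate values", "invalid_sd")
  out <- mu + spec$K * sd
  if (model$mean$outcome_log) out <- exp(out)
  rng <- model$mean$fit_range
  attr(out, "extrapolated") <- if (is.null(rng)) rep(FALSE, length(x))
                               else x < rng[1] | x > rng[2]
  out
}

#' Per-observation z scores against a mean/SD model
#'
#' @param model A [mean_sd_model()] for the observations' outcome.
#' @param obs An [observation_set()] (or data frame with `crl_mm` and
#'   `ga_weeks` columns).
#' @return Numeric vector `z = (outcome_on_modelled_scale - mean(x)) / sd(x)`.
#' @export
zscores <- function(model, obs) {
  v <- obs_xy(model, obs)
  y <- if (model$mean$outcome_log) log(v$y) else v$y
  sd <- predict(model$sd, v$x)
  if (any(sd <= 0))
    cd_stop("predicted SD is non-positive at some covariate values", "invalid_sd")
  (y - predict(model$mean, v$x)) / sd
}

# map an observation set onto a model's covariate/outcome roles
obs_xy <- function(model, obs) {
  cov <- model$mean$covariate_name
  out <- model$outcome_name
  if (!all(c(cov, out) %in% names(obs)))
    cd_stop(sprintf("observations lack the model's columns (%s, %s)", cov, out),
            "invalid_input")
  list(x = obs[[cov]], y = obs[[out]])
}
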