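# Fractional-polynomial (FP) regression of a mean and of a residual SD,
# following the Royston-Altman power family {-2, -1, -0.5, 0, 0.5, 1, 2, 3}
# with power 0 meaning ln(x) and a repeated power p meaning (x^p, x^p ln x).

#' The fractional-polynomial power set
#'
#' @return Numeric vector of the eight admissible FP powers. Power 0 denotes
#'   the natural-log term.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

cd_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(paste0("crldating_", class), "crldating_error"),
                      call = call))
}

#' Construct a fractional-polynomial model
#'
#' An FP model of degree m (m = 0, 1 or 2) represents
#' `intercept + sum_j coef_j * H_j(x)` where `H_j` are the FP basis terms for
#' the given powers: `x^p` for power `p`, `ln x` for power 0, and for a
#' repeated power `p` the pair `x^p` and `x^p ln x`.
#'
#' @param powers Numeric vector of length 0, 1 or 2; elements from
#'   [fp_powers()], non-decreasing.
#' @param coefficients Numeric vector, one coefficient per power.
#' @param intercept Single numeric intercept.
#' @param outcome_log Logical; `TRUE` when the outcome is modelled on the
#'   natural-log scale (predictions are on that modelled scale).
#' @param covariate_name Label for the covariate (e.g. `"crl_mm"`).
#' @param fit_range Length-2 numeric `[min, max]` of the covariate over which
#'   the model was fitted, or `NULL` for an analytic (closed-form) model.
#' @param selection Optional list recording the power-search trace.
#' @return An object of class `fp_model`.
#' @export
fp_model <- function(powers, coefficients, intercept, outcome_log = FALSE,
                     covariate_name = "x", fit_range = NULL, selection = NULL) {
  powers <- as.numeric(powers)
  coefficients <- as.numeric(coefficients)
  if (length(powers) > 2L)
    cd_stop("FP degree must be at most 2", "invalid_input")
  if (!all(powers %in% fp_powers()))
    cd_stop("powers must belong to {-2, -1, -0.5, 0, 0.5, 1, 2, 3}", "invalid_input")
  if (is.unsorted(powers))
    cd_stop("powers must be non-decreasing", "invalid_input")
  if (length(coefficients) != length(powers))
    cd_stop("one coefficient is required per power", "invalid_input")
  if (length(intercept) != 1L || !is.finite(intercept))
    cd_stop("intercept must be a single finite number", "invalid_input")
  if (!is.null(fit_range)) {
    fit_range <- as.numeric(fit_range)
    if (length(fit_range) != 2L || fit_range[1] > fit_range[2])
      cd_stop("fit_range must be [min, max]", "invalid_input")
  }
  structure(list(powers = powers, coefficients = coefficients,
                 intercept = as.numeric(intercept),
                 outcome_log = isTRUE(outcome_log),
                 covariate_name = covariate_name,
                 fit_range = fit_range, selection = selection),
            class = "fp_model")
}

# FP basis matrix for a sorted power vector; x must be > 0.
fp_design <- function(x, powers) {
  if (any(!is.finite(x)) || any(x <= 0))
    cd_stop("FP covariate values must be finite and > 0", "invalid_input")
  m <- length(powers)
  if (m == 0L) return(matrix(numeric(0), nrow = length(x), ncol = 0))
  one <- function(p) if (p == 0) log(x) else x^p
  if (m == 1L) return(cbind(one(powers[1])))
  h1 <- one(powers[1])
  h2 <- if (powers[2] == powers[1]) h1 * log(x) else one(powers[2])
  cbind(h1, h2)
}

#' Evaluate an FP model
#'
#' @param object An [fp_model()].
#' @param x Positive covariate values.
#' @param ... Unused.
#' @return Predicted values on the modelled scale (the log scale when
#'   `outcome_log` is `TRUE`; use [predict_centile()] for natural-scale
#'   centiles of a mean/SD pair).
#' @export
predict.fp_model <- function(object, x, ...) {
  X <- fp_design(x, object$powers)
  rep_len(object$intercept, length(x)) +
    (if (ncol(X)) drop(X %*% object$coefficients) else 0)
}

#' @export
print.fp_model <- function(x, ...) {
  deg <- length(x$powers)
  cat(sprintf("Fractional polynomial model (degree %d%s)\n", deg,
              if (deg) paste0(", powers ", paste(x$powers, collapse = ", ")) else ""))
  cat(sprintf("  outcome scale: %s\n", if (x$outcome_log) "natural log" else "natural"))
  terms <- character(0)
  if (deg) {
    lab <- fp_term_labels(x$powers, x$covariate_name)
    terms <- sprintf("%+.6g*%s", x$coefficients, lab)
  }
  cat("  ", paste(c(sprintf("%.6g", x$intercept), terms), collapse = " "), "\n", sep = "")
  if (!is.null(x$fit_range))
    cat(sprintf("  fitted over %s in [%g, %g]\n", x$covariate_name,
                x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

fp_term_labels <- function(powers, name) {
  if (length(powers) == 2 && powers[1] == powers[2]) {
    b <- if (powers[1] == 0) sprintf("ln(%s)", name) else sprintf("%s^%g", name, powers[1])
    return(c(b, paste0(b, "*ln(", name, ")")))
  }
  vapply(powers, function(p) if (p == 0) sprintf("ln(%s)", name)
         else sprintf("%s^%g", name, p), "")
}

# all candidate power tuples in deterministic (degree, lexicographic) order
fp_candidates <- function(max_degree, include_constant = FALSE) {
  out <- list()
  if (include_constant) out <- c(out, list(numeric(0)))
  pw <- fp_powers()
  out <- c(out, lapply(pw, function(p) p))
  if (max_degree >= 2) {
    for (i in seq_along(pw)) for (j in i:length(pw))
      out <- c(out, list(c(pw[i], pw[j])))
  }
  out
}

# OLS on the FP basis; returns coefficients, intercept and RSS
fp_ols <- function(x, y, powers) {
  X <- cbind(1, fp_design(x, powers))
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    cd_stop("singular FP design (degenerate covariate?)", "degenerate_design")
  rss <- sum(fit$residuals^2)
  list(intercept = unname(fit$coefficients[1]),
       coefficients = unname(fit$coefficients[-1]),
       rss = rss, rank = fit$rank)
}

# Gaussian deviance up to a constant, floored so that numerically perfect
# fits compare as ties rather than producing spurious chi-squared signals.
fp_deviance <- function(rss, n, floor) n * log(max(rss, floor) / n)

fp_search <- function(x, y, max_degree, include_constant = FALSE) {
  cands <- fp_candidates(max_degree, include_constant)
  floor_ <- 1e-16 * (sum((y - mean(y))^2) + .Machine$double.eps)
  n <- length(y)
  fits <- lapply(cands, function(p) {
    f <- tryCatch(fp_ols(x, y, p), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    f$powers <- p
    f$deviance <- fp_deviance(f$rss, n, floor_)
    f
  })
  fits[!vapply(fits, is.null, TRUE)]
}

# best fit among a subset, ties (within 1e-8 in deviance) broken by lower
# degree then lexicographically earlier powers -- guaranteed by search order
best_of <- function(fits) {
  stopifnot(length(fits) > 0)
  best <- fits[[1]]
  for (f in fits[-1]) if (f$deviance < best$deviance - 1e-8) best <- f
  best
}

select_fp <- function(fits, max_degree, alpha, method, include_constant = FALSE) {
  degs <- vapply(fits, function(f) length(f$powers), 0L)
  if (method == "deviance") {
    chosen <- best_of(fits)
    trace <- list(method = "deviance", alpha = NA_real_)
    return(list(fit = chosen, trace = trace))
  }
  # closed-test function-selection procedure at level alpha
  pick <- function(d) if (any(degs == d)) best_of(fits[degs == d]) else NULL
  lin <- Filter(function(f) identical(f$powers, 1), fits)
  lin <- if (length(lin)) lin[[1]] else NULL
  const <- if (include_constant) pick(0L) else NULL
  b1 <- pick(1L)
  b2 <- if (max_degree >= 2) pick(2L) else NULL
  top <- b2 %||% b1 %||% const
  if (is.null(top)) cd_stop("no FP candidate available", "degenerate_design")
  top_df <- 2 * length(top$powers)  # powers + coefficients beyond intercept
  crit <- function(diff_dev, df) diff_dev > stats::qchisq(1 - alpha, df)
  steps <- character(0)
  chosen <- NULL
  if (!is.null(const) && top_df > 0) {
    if (!crit(const$deviance - top$deviance, top_df)) {
      chosen <- const
      steps <- c(steps, "constant not rejected against best FP")
    }
  }
  if (is.null(chosen) && !is.null(lin) && length(top$powers) >= 1) {
    if (!crit(lin$deviance - top$deviance, top_df - 1)) {
      chosen <- lin
      steps <- c(steps, "linear not rejected against best FP")
    }
  }
  if (is.null(chosen)) {
    if (!is.null(b2) && !is.null(b1)) {
      if (crit(b1$deviance - b2$deviance, 2)) {
        chosen <- b2
        steps <- c(steps, "degree 2 improves on best degree 1")
      } else {
        chosen <- b1
        steps <- c(steps, "best degree 1 retained")
      }
    } else chosen <- top
  }
  list(fit = chosen,
       trace = list(method = "closed_test", alpha = alpha, steps = steps))
}

# Drop candidate fits whose curve is implausible over a stated covariate
# range: optionally non-increasing (on the modelled scale) or non-positive.
# Used when a fit is destined for extrapolation beyond its data.
filter_plausible <- function(fits, range, increasing = FALSE, positive = FALSE,
                             n_grid = 201L) {
  grid <- seq(range[1], range[2], length.out = n_grid)
  keep <- vapply(fits, function(f) {
    X <- fp_design(grid, f$powers)
    yhat <- f$intercept + if (ncol(X)) drop(X %*% f$coefficients) else 0
    ok <- TRUE
    if (increasing && length(f$powers)) ok <- all(diff(yhat) > 0)
    if (increasing && !length(f$powers)) ok <- FALSE
    if (ok && positive) ok <- all(yhat > 0)
    ok
  }, TRUE)
  fits[keep]
}

#' Fit an FP model to a conditional mean
#'
#' Performs an exhaustive least-squares search over fractional-polynomial
#' models of degree 1 (8 candidates) and, when `max_degree = 2`, degree 2
#' (36 candidates including repeated powers), then selects a model either by
#' the closed-test function-selection procedure at level `alpha` (default) or
#' by lowest deviance.
#'
#' @param x Covariate values, all > 0.
#' @param y Outcome values; when `outcome_log = TRUE` they must be > 0 and the
#'   fit is performed on `ln y`.
#' @param outcome_log Model the outcome on the natural-log scale?
#' @param max_degree Maximum FP degree, 1 or 2.
#' @param powers Optional fixed power vector; skips the search.
#' @param select `"closed_test"` (deviance-difference chi-squared tests
#'   comparing best degree-2 vs best degree-1 vs linear) or `"deviance"`
#'   (global minimum deviance).
#' @param alpha Significance level for the closed test.
#' @param covariate_name Label stored in the returned model.
#' @param constrain Optional plausibility constraint applied before selection
#'   when the fit will be extrapolated: a list with `range` (covariate
#'   interval to screen over) and logicals `increasing` (curve strictly
#'   increasing on the modelled scale) and `positive` (curve positive).
#'   Candidates violating it are discarded.
#' @return An [fp_model()] with `fit_range = range(x)` and a `selection` trace.
#' @export
fit_fp_mean <- function(x, y, outcome_log = FALSE, max_degree = 2,
                        powers = NULL, select = c("closed_test", "deviance"),
                        alpha = 0.05, covariate_name = "x", constrain = NULL) {
  select <- match.arg(select)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    cd_stop("x and y must have equal length", "invalid_input")
  if (length(x) < 10L)
    cd_stop("at least 10 observations are required", "invalid_input")
  if (any(!is.finite(x)) || any(x <= 0))
    cd_stop("covariate values must be finite and > 0", "invalid_input")
  if (outcome_log) {
    if (any(!is.finite(y)) || any(y <= 0))
      cd_stop("outcome must be > 0 for a log-scale fit", "invalid_input")
    y <- log(y)
  }
  if (!max_degree %in% c(1, 2))
    cd_stop("max_degree must be 1 or 2", "invalid_input")
  if (!is.null(powers)) {
    f <- fp_ols(x, y, powers)
    return(fp_model(powers, f$coefficients, f$intercept, outcome_log,
                    covariate_name, range(x),
                    selection = list(method = "fixed", rss = f$rss)))
  }
  fits <- fp_search(x, y, max_degree)
  if (!length(fits))
    cd_stop("no FP candidate could be fitted (degenerate design)", "degenerate_design")
  if (!is.null(constrain)) {
    # screen over the union of the stated range and the data range, so the
    # constraint is consistent with the fitted support
    fits <- filter_plausible(fits, range(c(constrain$range, x)),
                             increasing = isTRUE(constrain$increasing),
                             positive = isTRUE(constrain$positive))
    if (!length(fits))
      cd_stop("no FP candidate satisfies the plausibility constraint",
              "degenerate_design")
  }
  sel <- select_fp(fits, max_degree, alpha, select)
  f <- sel$fit
  fp_model(f$powers, f$coefficients, f$intercept, outcome_log, covariate_name,
           range(x),
           selection = c(sel$trace, list(rss = f$rss, deviance = f$deviance)))
}

#' Fit an FP model to a residual SD
#'
#' Regresses half-normal-scaled absolute residuals, `|r| * sqrt(pi/2)`, on the
#' covariate by least squares over FP candidates up to `max_degree`, allowing
#' a degree-0 (constant SD) model. The sqrt(pi/2) factor makes the fitted
#' curve an unbiased estimate of the residual SD under normal errors.
#'
#' @param x Covariate values, all > 0 (same observations as the mean fit).
#' @param residuals Residuals from the mean model, on its modelled scale.
#' @param max_degree Maximum FP degree for the SD curve (default 1).
#' @param select,alpha As in [fit_fp_mean()]; the closed test here also
#'   compares against the constant-SD model.
#' @param covariate_name Label stored in the returned model.
#' @param positive_range Optional covariate interval over which candidate SD
#'   curves must stay positive (use when the SD will be extrapolated); the fit
#'   range itself is always checked.
#' @param extra_filter Optional predicate applied to each candidate fit (a
#'   list with `powers`, `coefficients`, `intercept`); candidates for which it
#'   returns `FALSE` are discarded before selection.
#' @return An [fp_model()] for the SD; predicted SD is checked to be positive
#'   over the fit range.
#' @export
fit_fp_sd <- function(x, residuals, max_degree = 1,
                      select = c("closed_test", "deviance"), alpha = 0.05,
                      covariate_name = "x", positive_range = NULL,
                      extra_filter = NULL) {
  select <- match.arg(select)
  x <- as.numeric(x); r <- as.numeric(residuals)
  if (length(x) != length(r))
    cd_stop("x and residuals must have equal length", "invalid_input")
  if (any(!is.finite(x)) || any(x <= 0))
    cd_stop("covariate values must be finite and > 0", "invalid_input")
  y <- abs(r) * sqrt(pi / 2)
  fits <- fp_search(x, y, max_degree, include_constant = TRUE)
  if (!is.null(positive_range)) {
    fits <- filter_plausible(fits, range(c(positive_range, x)), positive = TRUE)
    if (!length(fits))
      cd_stop("no SD candidate stays positive over the required range",
              "invalid_sd")
  }
  if (!is.null(extra_filter)) {
    fits <- Filter(extra_filter, fits)
    if (!length(fits))
      cd_stop("no SD candidate satisfies the plausibility constraint",
              "invalid_sd")
  }
  sel <- select_fp(fits, max_degree, alpha, select, include_constant = TRUE)
  f <- sel$fit
  m <- fp_model(f$powers, f$coefficients, f$intercept, FALSE, covariate_name,
                range(x),
                selection = c(sel$trace, list(rss = f$rss, deviance = f$deviance)))
  grid <- seq(min(x), max(x), length.out = 101)
  if (any(predict(m, grid) <= 0))
    cd_stop("fitted SD model is non-positive within the fit range", "invalid_sd")
  m
}
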