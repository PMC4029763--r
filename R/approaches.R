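# Fitting size and dating charts, and the three strategies for fitting a
# dating model (GA as a function of CRL) when GA is truncated by design.

#' Fit a size model (CRL as a function of GA)
#'
#' FP mean fit of CRL (mm) on GA (weeks) on the natural scale, plus an FP fit
#' of the residual SD. Truncation of GA does not bias this direction of
#' modelling, which all truncation-handling strategies exploit.
#'
#' @param obs An [observation_set()].
#' @param max_degree Maximum FP degree for the mean (default 2).
#' @param sd_max_degree Maximum FP degree for the SD (default 1).
#' @param select,alpha Passed to [fit_fp_mean()] / [fit_fp_sd()].
#' @param plausible_range Optional GA interval (weeks) over which the fitted
#'   curves must remain plausible -- mean strictly increasing and positive, SD
#'   positive, and the outer centiles `mean +/- K * sd` strictly increasing.
#'   Set this to the extrapolation range when the model will be used beyond
#'   its data (the augmentation and axis-interchange strategies do).
#' @param centile_K Normal equivalent deviate defining the outer centiles
#'   screened by the plausibility constraint (default the exact 97th-centile
#'   quantile).
#' @return A `size_model` ([mean_sd_model()]).
#' @export
fit_size_model <- function(obs, max_degree = 2, sd_max_degree = 1,
                           select = "closed_test", alpha = 0.05,
                           plausible_range = NULL,
                           centile_K = stats::qnorm(0.97)) {
  x <- obs$ga_weeks; y <- obs$crl_mm
  if (is.null(plausible_range)) {
    m <- fit_fp_mean(x, y, outcome_log = FALSE, max_degree = max_degree,
                     select = select, alpha = alpha, covariate_name = "ga_weeks")
    s <- fit_fp_sd(x, y - predict(m, x), max_degree = sd_max_degree,
                   select = select, alpha = alpha, covariate_name = "ga_weeks")
    return(mean_sd_model(m, s, outcome_name = "crl_mm", class = "size_model"))
  }
  # Plausibility-constrained selection over the extrapolation range: the mean
  # must be positive and strictly increasing, the SD positive, and the outer
  # centiles mean +/- K*sd strictly increasing with a positive lower centile.
  # Mean and SD are screened jointly: a mean candidate for which no SD
  # candidate yields plausible centiles is itself rejected and the selection
  # rerun on the remaining candidates.
  if (length(x) < 10L)
    cd_stop("at least 10 observations are required", "invalid_input")
  cands <- fp_search(x, y, max_degree)
  cands <- filter_plausible(cands, plausible_range, increasing = TRUE,
                            positive = TRUE)
  grid <- seq(plausible_range[1], plausible_range[2], length.out = 201)
  rejected <- 0L
  repeat {
    if (!length(cands))
      cd_stop("no jointly plausible mean/SD pair over the extrapolation range",
              "degenerate_design")
    sel <- select_fp(cands, max_degree, alpha, select)
    mf <- sel$fit
    mu <- mf$intercept + {
      X <- fp_design(grid, mf$powers)
      if (ncol(X)) drop(X %*% mf$coefficients) else 0
    }
    r <- y - (mf$intercept + {
      X <- fp_design(x, mf$powers)
      if (ncol(X)) drop(X %*% mf$coefficients) else 0
    })
    plausible_centiles <- function(f) {
      X <- fp_design(grid, f$powers)
      s <- f$intercept + if (ncol(X)) drop(X %*% f$coefficients) else 0
      lo <- mu - centile_K * s
      all(diff(mu + centile_K * s) > 0) && all(diff(lo) > 0) && all(lo > 0)
    }
    s <- tryCatch(
      fit_fp_sd(x, r, max_degree = sd_max_degree, select = select,
                alpha = alpha, covariate_name = "ga_weeks",
                positive_range = plausible_range,
                extra_filter = plausible_centiles),
      crldating_invalid_sd = function(e) NULL)
    if (!is.null(s)) break
    cands <- Filter(function(f) !identical(f$powers, mf$powers), cands)
    rejected <- rejected + 1L
  }
  m <- fp_model(mf$powers, mf$coefficients, mf$intercept, FALSE, "ga_weeks",
                range(x),
                selection = c(sel$trace,
                              list(rss = mf$rss, deviance = mf$deviance,
                                   plausibility_rejections = rejected)))
  mean_sd_model(m, s, outcome_name = "crl_mm", class = "size_model")
}

#' Fit a dating model (GA as a function of CRL) directly
#'
#' FP mean fit of ln(GA) on CRL plus an FP fit of the SD of ln(GA). Valid as-is
#' only on data whose GA range is not truncated; on truncated data use one of
#' [run_approach1()], [run_approach2()] or [run_approach3()].
#'
#' @inheritParams fit_size_model
#' @param plausible_range Optional CRL interval (mm) over which the fitted
#'   median must be strictly increasing and the SD positive; set to the
#'   reporting/extrapolation range when the fit is extrapolated.
#' @return A `dating_model` ([mean_sd_model()]).
#' @export
fit_dating_model <- function(obs, max_degree = 2, sd_max_degree = 1,
                             select = "closed_test", alpha = 0.05,
                             plausible_range = NULL) {
  constrain <- if (!is.null(plausible_range))
    list(range = plausible_range, increasing = TRUE)
  m <- fit_fp_mean(obs$crl_mm, obs$ga_weeks, outcome_log = TRUE,
                   max_degree = max_degree, select = select, alpha = alpha,
                   covariate_name = "crl_mm", constrain = constrain)
  r <- log(obs$ga_weeks) - predict(m, obs$crl_mm)
  s <- fit_fp_sd(obs$crl_mm, r, max_degree = sd_max_degree, select = select,
                 alpha = alpha, covariate_name = "crl_mm",
                 positive_range = plausible_range)
  mean_sd_model(m, s, outcome_name = "ga_weeks", class = "dating_model")
}

#' Configuration for the low-end augmentation approach
#'
#' @param augment_days Gestational days at which to simulate CRL below the
#'   truncation window; default 49:62 (7+0 through 8+6 weeks).
#' @param n_per_day Simulated CRL draws per day (default 100).
#' @param restrict_crl CRL window (mm) to which the dating fit is restricted
#'   before extrapolation; default c(20, 65). The 65 mm ceiling reflects the
#'   smallest CRL seen at the 14-week truncation bound, the 20 mm floor the
#'   best-performing lower cutoff.
#' @param sensitivity_cutoffs Lower cutoffs (mm) examined by
#'   [sensitivity_lower_cutoff()].
#' @return A list of class `approach1_config`.
#' @export
approach1_config <- function(augment_days = 49:62, n_per_day = 100,
                             restrict_crl = c(20, 65),
                             sensitivity_cutoffs = c(10, 15, 20)) {
  if (length(restrict_crl) != 2L || restrict_crl[1] >= restrict_crl[2])
    cd_stop("restrict_crl must be [low, high] with low < high", "invalid_input")
  structure(list(augment_days = augment_days, n_per_day = n_per_day,
                 restrict_crl = as.numeric(restrict_crl),
                 sensitivity_cutoffs = as.numeric(sensitivity_cutoffs)),
            class = "approach1_config")
}

#' Configuration for the two-sided augmentation approach
#'
#' @param augment_days_low,augment_days_high Gestational days at which to
#'   simulate CRL below and above the truncation window; defaults 49:62
#'   (7+0 to 8+6) and 98:119 (14+0 to 17+0).
#' @param n_per_day Simulated CRL draws per day (default 100).
#' @return A list of class `approach2_config`.
#' @export
approach2_config <- function(augment_days_low = 49:62,
                             augment_days_high = 98:119, n_per_day = 100) {
  structure(list(augment_days_low = augment_days_low,
                 augment_days_high = augment_days_high,
                 n_per_day = n_per_day),
            class = "approach2_config")
}

#' Configuration for the axis-interchange approach
#'
#' @param ga_eval_days Gestational days over which fitted size-chart centiles
#'   are evaluated before the axes are interchanged; default 49:119 (7 to 17
#'   weeks), one point per day.
#' @param levels Centile levels evaluated; default `c(0.03, 0.5, 0.97)`.
#' @param sd_max_degree Maximum FP degree of the recovered SD curve.
#' @return A list of class `approach3_config`.
#' @export
approach3_config <- function(ga_eval_days = 49:119,
                             levels = c(0.03, 0.5, 0.97), sd_max_degree = 1) {
  levels <- sort(as.numeric(levels))
  if (length(levels) != 3L || any(levels <= 0) || any(levels >= 1) ||
      abs(levels[2] - 0.5) > 1e-12)
    cd_stop("levels must be three probabilities with 0.5 in the middle",
            "invalid_input")
  if (diff(range(ga_eval_days)) < 1)
    cd_stop("ga_eval_days must span a non-trivial range", "invalid_input")
  structure(list(ga_eval_days = as.numeric(ga_eval_days), levels = levels,
                 sd_max_degree = sd_max_degree),
            class = "approach3_config")
}

#' Approach 1: low-end augmentation, restriction and extrapolation
#'
#' Fits a size chart to the truncated data, simulates CRL below the truncation
#' window from it (100 draws per gestational day, 7+0 to 8+6 by default),
#' fits a dating model to the augmented data restricted to a CRL window
#' (20 to 65 mm by default), and relies on FP extrapolation beyond that window.
#'
#' @param obs A GA-truncated [observation_set()].
#' @param cfg An [approach1_config()].
#' @param seed Integer seed for the augmentation draws.
#' @param window The [truncation_window()] (used to tag augmentation rows).
#' @param plausible_crl CRL interval (mm) over which the dating fit must stay
#'   plausible (median increasing, SD positive) since it is extrapolated well
#'   beyond the restriction window; default 10 to 105 mm, covering the
#'   reporting grid.
#' @return A `dating_model` whose `fit_range` records the CRL restriction, so
#'   centiles computed beyond it are flagged as extrapolated. The `"approach"`
#'   attribute records the configuration, the intermediate size model and the
#'   fitting data set (the set on which goodness-of-fit coverage is counted).
#' @export
run_approach1 <- function(obs, cfg = approach1_config(), seed = 20131207,
                          window = truncation_window(),
                          plausible_crl = c(10, 105)) {
  aug <- NULL
  if (length(cfg$augment_days)) {
    ga_lo <- min(cfg$augment_days) / 7
    size <- fit_size_model(obs, plausible_range = c(ga_lo, max(obs$ga_weeks)))
    aug <- simulate_from_size(size, cfg$augment_days, cfg$n_per_day, seed, window)
  } else size <- fit_size_model(obs)
  all <- if (is.null(aug)) obs else bind_observations(obs, aug)
  keep <- all$crl_mm >= cfg$restrict_crl[1] & all$crl_mm <= cfg$restrict_crl[2]
  restricted <- as_observation_set(as.data.frame(all)[keep, , drop = FALSE])
  if (nrow(restricted) < 10L)
    cd_stop("fewer than 10 observations in the CRL restriction window",
            "insufficient_data")
  model <- fit_dating_model(restricted, plausible_range = plausible_crl)
  attr(model, "approach") <- list(name = "approach1", config = cfg, seed = seed,
                                  size_model = size, data = restricted,
                                  n_augmented = if (is.null(aug)) 0L else nrow(aug))
  model
}

#' Approach 2: augmentation at both ends of the GA distribution
#'
#' Fits a size chart to the truncated data, simulates CRL below and above the
#' truncation window (100 draws per gestational day, 7+0 to 8+6 and 14+0 to
#' 17+0 by default), and fits the dating model to the full augmented data set
#' with no CRL restriction.
#'
#' @param obs A GA-truncated [observation_set()].
#' @param cfg An [approach2_config()].
#' @param seed Integer seed for the augmentation draws.
#' @param window The [truncation_window()].
#' @param plausible_crl As in [run_approach1()].
#' @return A `dating_model`.
#' @export
run_approach2 <- function(obs, cfg = approach2_config(), seed = 20131207,
                          window = truncation_window(),
                          plausible_crl = c(10, 105)) {
  days <- c(cfg$augment_days_low, cfg$augment_days_high)
  all <- if (length(days)) {
    size <- fit_size_model(obs, plausible_range = range(c(days / 7, obs$ga_weeks)))
    aug <- simulate_from_size(size, days, cfg$n_per_day, seed, window)
    bind_observations(obs, aug)
  } else {
    size <- fit_size_model(obs)
    obs
  }
  model <- fit_dating_model(all, plausible_range = plausible_crl)
  attr(model, "approach") <- list(name = "approach2", config = cfg, seed = seed,
                                  size_model = size, data = all,
                                  n_augmented = nrow(all) - nrow(obs))
  model
}

#' Approach 3: interchanging the axes of a fitted size chart
#'
#' Fits a size chart to the truncated data, evaluates its outer and median CRL
#' centiles on a daily GA grid (extrapolating beyond the data), interchanges
#' the axes, regresses ln(GA) on FP functions of the predicted CRL coordinates
#' for each centile set, and recovers an SD curve from the averaged half-
#' spreads of the outer centile regressions. No simulation is involved.
#'
#' @param obs A GA-truncated [observation_set()].
#' @param cfg An [approach3_config()].
#' @return A `dating_model` (median = the 50th-centile regression; SD = the
#'   recovered curve).
#' @export
run_approach3 <- function(obs, cfg = approach3_config()) {
  size <- fit_size_model(obs,
                         plausible_range = range(c(cfg$ga_eval_days / 7,
                                                   obs$ga_weeks)))
  ga <- cfg$ga_eval_days / 7
  coords <- lapply(cfg$levels, function(l) {
    crl <- as.numeric(predict_centile(size, ga, level = l))
    if (any(diff(crl) <= 0))
      cd_stop(sprintf(
        "predicted CRL centile (level %.2f) is not strictly increasing in GA; axis interchange is invalid",
        l), "inversion_invalid")
    data.frame(crl_mm = crl, ga_weeks = ga)
  })
  fits <- lapply(coords, function(d)
    fit_fp_mean(d$crl_mm, d$ga_weeks, outcome_log = TRUE,
                covariate_name = "crl_mm"))
  median_fit <- fits[[2]]
  # the low-CRL-centile coordinates lie left of the median, so after the
  # interchange they trace the *upper* GA centile at fixed CRL
  lo <- max(vapply(coords, function(d) min(d$crl_mm), 0))
  hi <- min(vapply(coords, function(d) max(d$crl_mm), 0))
  grid <- seq(ceiling(lo), floor(hi))
  ga_c97 <- exp(predict(fits[[1]], grid))
  ga_c50 <- exp(predict(median_fit, grid))
  ga_c3 <- exp(predict(fits[[3]], grid))
  K <- stats::qnorm(cfg$levels[3])
  sd_fit <- recover_sd_from_centiles(grid, ga_c3, ga_c50, ga_c97, K = K,
                                     max_degree = cfg$sd_max_degree,
                                     covariate_name = "crl_mm",
                                     positive_range = range(coords[[2]]$crl_mm))
  model <- mean_sd_model(median_fit, sd_fit, outcome_name = "ga_weeks",
                         class = "dating_model")
  attr(model, "approach") <- list(name = "approach3", config = cfg,
                                  size_model = size, data = obs,
                                  centile_fits = fits)
  model
}

#' Recover an SD curve from three centile curves
#'
#' On the log scale of a lognormal outcome, each outer centile is offset from
#' the median by `K * SD`, so the SD at a covariate value can be estimated
#' twice -- from the upper and from the lower half-spread -- and averaged:
#' `SD = ((ln c97 - ln c50)/K + (ln c50 - ln c3)/K) / 2`. The averaged values
#' are then summarised by an FP regression on the covariate.
#'
#' @param x Covariate values (CRL in mm).
#' @param c3,c50,c97 Centile curves of the outcome at `x`, with
#'   `c3 < c50 < c97` pointwise.
#' @param K Normal equivalent deviate of the outer centiles (default the exact
#'   97th-centile quantile).
#' @param max_degree Maximum FP degree of the SD regression (default 1; a
#'   constant model is also considered).
#' @param covariate_name Label stored in the returned model.
#' @param positive_range Covariate interval over which candidate SD curves
#'   must stay positive; defaults to `range(x)` and is widened to include it.
#' @return An [fp_model()] for the SD of the log outcome.
#' @export
recover_sd_from_centiles <- function(x, c3, c50, c97, K = stats::qnorm(0.97),
                                     max_degree = 1, covariate_name = "x",
                                     positive_range = NULL) {
  if (any(!(c3 < c50 & c50 < c97)))
    cd_stop("centile curves must satisfy c3 < c50 < c97 pointwise",
            "invalid_centiles")
  sd_vals <- ((log(c97) - log(c50)) / K + (log(c50) - log(c3)) / K) / 2
  fits <- fp_search(x, sd_vals, max_degree, include_constant = TRUE)
  fits <- filter_plausible(fits, range(c(positive_range, x)), positive = TRUE)
  if (!length(fits))
    cd_stop("no positive FP candidate could be fitted to the SD values",
            "invalid_sd")
  sel <- select_fp(fits, max_degree, 0.05, "closed_test", include_constant = TRUE)
  f <- sel$fit
  m <- fp_model(f$powers, f$coefficients, f$intercept, FALSE, covariate_name,
                range(c(positive_range, x)),
                selection = c(sel$trace, list(rss = f$rss)))
  if (any(predict(m, seq(min(x), max(x), length.out = 101)) <= 0))
    cd_stop("recovered SD model is non-positive within the fit range", "invalid_sd")
  m
}

#' Sensitivity of the low-end augmentation approach to the lower CRL cutoff
#'
#' Reruns [run_approach1()] with each candidate lower cutoff for the CRL
#' restriction window and summarises median-GA agreement with a reference
#' dating equation over a reporting grid.
#'
#' @param obs A GA-truncated [observation_set()].
#' @param base_cfg An [approach1_config()]; its upper restriction bound and
#'   augmentation settings are reused for every cutoff.
#' @param reference A reference `dating_model` (e.g. [verburg_equation()]).
#' @param seed Integer seed (same augmentation draws for every cutoff).
#' @param crl_grid Reporting grid in mm (default 20 to 100 by 5).
#' @return A data frame with one row per cutoff: `cutoff_mm`,
#'   `max_abs_diff_days`, `mean_diff_days` for the median centile.
#' @export
sensitivity_lower_cutoff <- function(obs, base_cfg = approach1_config(),
                                     reference = verburg_equation(),
                                     seed = 20131207,
                                     crl_grid = seq(20, 100, by = 5)) {
  out <- lapply(base_cfg$sensitivity_cutoffs, function(cut) {
    cfg <- base_cfg
    cfg$restrict_crl <- c(cut, base_cfg$restrict_crl[2])
    model <- run_approach1(obs, cfg, seed)
    tab <- compare_to_reference(model, reference, crl_grid)
    s <- agreement_summary(tab, range(crl_grid), centile = "median")
    data.frame(cutoff_mm = cut, max_abs_diff_days = s$max_abs_diff_days,
               mean_diff_days = s$mean_diff_days)
  })
  do.call(rbind, out)
}
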