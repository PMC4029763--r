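# Simulation engine: draw (CRL, GA) observation sets from a closed-form
# dating equation or from a fitted size model, and apply GA truncation.

#' Construct an observation set
#'
#' A plain data frame of paired measurements with a provenance flag:
#' `crl_mm` (crown-rump length, mm), `ga_weeks` (gestational age, weeks) and
#' `source` (`"observed"`, `"simulated_low"` or `"simulated_high"`).
#'
#' @param crl_mm,ga_weeks Positive numeric vectors of equal length.
#' @param source Provenance flag, recycled; one of `"observed"`,
#'   `"simulated_low"`, `"simulated_high"`.
#' @param metadata Optional named list (seed, generating model, ...), kept as
#'   an attribute and preserved by [truncate_ga()].
#' @return A data frame of class `observation_set`.
#' @export
observation_set <- function(crl_mm, ga_weeks, source = "observed",
                            metadata = list()) {
  crl_mm <- as.numeric(crl_mm); ga_weeks <- as.numeric(ga_weeks)
  if (length(crl_mm) != length(ga_weeks))
    cd_stop("crl_mm and ga_weeks must have equal length", "invalid_input")
  if (any(!is.finite(crl_mm)) || any(crl_mm <= 0))
    cd_stop("crl_mm must be finite and > 0", "invalid_input")
  if (any(!is.finite(ga_weeks)) || any(ga_weeks <= 0))
    cd_stop("ga_weeks must be finite and > 0", "invalid_input")
  source <- rep_len(as.character(source), length(crl_mm))
  bad <- !source %in% c("observed", "simulated_low", "simulated_high")
  if (any(bad))
    cd_stop("source must be observed, simulated_low or simulated_high",
            "invalid_input")
  out <- data.frame(crl_mm = crl_mm, ga_weeks = ga_weeks, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("observation_set", "data.frame")
  attr(out, "metadata") <- metadata
  out
}

as_observation_set <- function(df, metadata = list()) {
  observation_set(df$crl_mm, df$ga_weeks, df$source %||% "observed", metadata)
}

#' Combine observation sets
#'
#' @param ... Observation sets (or compatible data frames).
#' @return A single [observation_set()]; metadata lists are concatenated.
#' @export
bind_observations <- function(...) {
  parts <- list(...)
  md <- do.call(c, lapply(parts, function(p) attr(p, "metadata") %||% list()))
  df <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)[
    , c("crl_mm", "ga_weeks", "source")]))
  rownames(df) <- NULL
  as_observation_set(df, metadata = md)
}

#' Truncation window for gestational age
#'
#' @param ga_low,ga_high Bounds in weeks, `ga_low < ga_high`. Defaults encode
#'   the clinical 9+0 to 13+6 week recruitment window as the half-open
#'   interval [9, 14).
#' @return A list with `ga_low`, `ga_high`, class `truncation_window`.
#' @export
truncation_window <- function(ga_low = 9, ga_high = 14) {
  if (!is.finite(ga_low) || ga_low >= ga_high)
    cd_stop("require ga_low < ga_high", "invalid_input")
  structure(list(ga_low = ga_low, ga_high = ga_high),
            class = "truncation_window")
}

# run code under a local RNG state so simulations are reproducible without
# disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.null(seed) && (!is.finite(seed) || seed != round(seed)))
    cd_stop("seed must be an integer", "invalid_input")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Simulate observations from a dating equation
#'
#' For each CRL value on the grid, draws `n_per_value` gestational ages with
#' `ln(GA) ~ Normal(mean(CRL), sd(CRL))` as the dating model specifies.
#'
#' @param eq A `dating_model` / [dating_equation()].
#' @param crl_grid CRL values in mm, all > 0. Default 5 to 110 mm in 1 mm
#'   steps, the grid that yields 10,600 observations at `n_per_value = 100`.
#' @param n_per_value Draws per grid value (default 100).
#' @param seed Integer seed (default 20131207).
#' @return An [observation_set()] of `length(crl_grid) * n_per_value` rows,
#'   all flagged `"observed"`.
#' @export
simulate_from_dating <- function(eq, crl_grid = 5:110, n_per_value = 100,
                                 seed = 20131207) {
  if (!inherits(eq, "dating_model"))
    cd_stop("eq must be a dating model", "invalid_input")
  crl_grid <- as.numeric(crl_grid)
  if (!length(crl_grid) || any(!is.finite(crl_grid)) || any(crl_grid <= 0))
    cd_stop("crl_grid values must be finite and > 0", "invalid_input")
  if (length(n_per_value) != 1L || !is.finite(n_per_value) || n_per_value < 1)
    cd_stop("n_per_value must be >= 1", "invalid_input")
  n_per_value <- as.integer(n_per_value)
  crl <- rep(crl_grid, each = n_per_value)
  mu <- predict(eq$mean, crl)
  sd <- predict(eq$sd, crl)
  ga <- with_seed(seed, exp(stats::rnorm(length(crl), mu, sd)))
  observation_set(crl, ga, "observed",
                  metadata = list(seed = seed, generator = "dating_equation",
                                  n_per_value = n_per_value,
                                  crl_grid = range(crl_grid)))
}

#' Simulate CRL observations from a size model (augmentation draws)
#'
#' For each gestational day on the grid, draws `n_per_day` CRL values as
#' `CRL ~ Normal(mean(GA), sd(GA))` from the fitted size model, typically to
#' augment a GA-truncated data set outside its truncation window. Negative or
#' zero CRL draws (possible in the normal tail at early GA) are rejected and
#' redrawn; the number of redraws is recorded in the metadata.
#'
#' @param model A `size_model` (outcome `crl_mm`, covariate `ga_weeks`).
#' @param ga_day_grid Gestational ages in days; converted to weeks as day/7.
#' @param n_per_day Draws per day (default 100).
#' @param seed Integer seed.
#' @param window A [truncation_window()] used only to tag rows as
#'   `"simulated_low"` (GA below the window) or `"simulated_high"`.
#' @return An [observation_set()] of `length(ga_day_grid) * n_per_day` rows.
#' @export
simulate_from_size <- function(model, ga_day_grid, n_per_day = 100,
                               seed = 20131207,
                               window = truncation_window()) {
  if (!inherits(model, "size_model"))
    cd_stop("model must be a size model", "invalid_input")
  ga_day_grid <- as.numeric(ga_day_grid)
  if (!length(ga_day_grid) || any(!is.finite(ga_day_grid)) || any(ga_day_grid <= 0))
    cd_stop("ga_day_grid values must be finite and > 0", "invalid_input")
  if (length(n_per_day) != 1L || !is.finite(n_per_day) || n_per_day < 1)
    cd_stop("n_per_day must be >= 1", "invalid_input")
  n_per_day <- as.integer(n_per_day)
  ga <- rep(ga_day_grid / 7, each = n_per_day)
  mu <- predict(model$mean, ga)
  sd <- predict(model$sd, ga)
  if (any(sd <= 0))
    cd_stop("size model SD is non-positive on the augmentation grid", "invalid_sd")
  redraws <- 0L
  crl <- with_seed(seed, {
    v <- stats::rnorm(length(ga), mu, sd)
    while (any(v <= 0)) {
      bad <- v <= 0
      redraws <- redraws + sum(bad)
      v[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    }
    v
  })
  source <- ifelse(ga < window$ga_low, "simulated_low", "simulated_high")
  observation_set(crl, ga, source,
                  metadata = list(seed = seed, generator = "size_model",
                                  n_per_day = n_per_day, redraws = redraws,
                                  ga_day_grid = range(ga_day_grid)))
}

#' Truncate an observation set by gestational age
#'
#' Retains rows with `ga_low <= ga_weeks < ga_high` (half-open, encoding e.g.
#' the 9+0 to 13+6 week window as [9, 14)). Order and metadata are preserved;
#' the operation is idempotent.
#'
#' @param obs An [observation_set()].
#' @param window A [truncation_window()].
#' @return The filtered [observation_set()] (possibly empty).
#' @export
truncate_ga <- function(obs, window = truncation_window()) {
  keep <- obs$ga_weeks >= window$ga_low & obs$ga_weeks < window$ga_high
  out <- as.data.frame(obs)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("observation_set", "data.frame")
  attr(out, "metadata") <- c(attr(obs, "metadata") %||% list(),
                             list(truncation = c(window$ga_low, window$ga_high)))
  out
}
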