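# File I/O: observation CSVs, model JSON, run configurations.

#' Read an observation set from CSV
#'
#' Expects columns `crl_mm` and `ga_weeks`; an optional `source` column
#' defaults to `"observed"`. Malformed rows (non-numeric or non-positive
#' values) are reported with their file line numbers.
#'
#' @param path CSV path.
#' @return An [observation_set()].
#' @export
read_observations <- function(path) {
  if (!file.exists(path))
    cd_stop(sprintf("file not found: %s", path), "parse")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("crl_mm", "ga_weeks")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cd_stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
            "parse")
  if (is.null(df$source)) df$source <- "observed"
  crl <- suppressWarnings(as.numeric(df$crl_mm))
  ga <- suppressWarnings(as.numeric(df$ga_weeks))
  bad <- which(!is.finite(crl) | crl <= 0 | !is.finite(ga) | ga <= 0)
  if (length(bad))
    cd_stop(sprintf(
      "invalid crl_mm/ga_weeks values (must be numeric and > 0) at line(s): %s",
      paste(bad + 1L, collapse = ", ")), "parse")
  observation_set(crl, ga, df$source, metadata = list(path = path))
}

#' Write an observation set to CSV
#'
#' @param obs An [observation_set()].
#' @param path Output CSV path.
#' @param metadata_path Optional path for a JSON sidecar with the set's
#'   metadata (seed, generating model, ...).
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, metadata_path = NULL) {
  utils::write.csv(as.data.frame(obs)[, c("crl_mm", "ga_weeks", "source")],
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path))
    jsonlite::write_json(attr(obs, "metadata") %||% list(), metadata_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

fp_to_list <- function(m) {
  list(powers = m$powers, coefficients = m$coefficients,
       intercept = m$intercept, outcome_log = m$outcome_log,
       covariate_name = m$covariate_name, fit_range = m$fit_range,
       selection = m$selection)
}

fp_from_list <- function(l) {
  fp_model(unlist(l$powers) %||% numeric(0),
           unlist(l$coefficients) %||% numeric(0),
           l$intercept, isTRUE(l$outcome_log), l$covariate_name,
           if (length(l$fit_range)) unlist(l$fit_range) else NULL,
           selection = l$selection)
}

#' Serialize a model to JSON
#'
#' Writes an [fp_model()] or [mean_sd_model()] (including `size_model` /
#' `dating_model`) to a documented JSON layout: FP models carry `powers`,
#' `coefficients`, `intercept`, `outcome_log`, `covariate_name`, `fit_range`
#' and the selection trace; paired models carry `mean` and `sd` sub-objects,
#' `outcome_name` and `model_class`.
#'
#' @param model The model object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "fp_model")) {
    c(list(type = "fp_model"), fp_to_list(model))
  } else if (inherits(model, "mean_sd_model")) {
    list(type = "mean_sd_model",
         model_class = setdiff(class(model), "mean_sd_model"),
         outcome_name = model$outcome_name,
         mean = fp_to_list(model$mean), sd = fp_to_list(model$sd))
  } else cd_stop("model must be an fp_model or mean_sd_model", "invalid_input")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path JSON path.
#' @return An [fp_model()] or [mean_sd_model()].
#' @export
read_model_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(l$type, "fp_model")) return(fp_from_list(l))
  if (identical(l$type, "mean_sd_model")) {
    cls <- setdiff(unlist(l$model_class), "mean_sd_model")
    return(mean_sd_model(fp_from_list(l$mean), fp_from_list(l$sd),
                         outcome_name = l$outcome_name,
                         class = if (length(cls)) cls else NULL))
  }
  cd_stop("unrecognised model JSON", "parse")
}

#' Configuration of a full truncation study run
#'
#' @param seed Master integer seed; stage seeds are derived as small offsets.
#' @param crl_grid Simulation CRL grid in mm.
#' @param n_per_value Simulated GA draws per CRL value.
#' @param window A [truncation_window()].
#' @param approach1,approach2,approach3 Stage configurations.
#' @param reporting_grid CRL grid (mm) for the comparison tables.
#' @param coverage_range CRL window (mm) for the coverage counts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 20131207, crl_grid = 5:110, n_per_value = 100,
                       window = truncation_window(),
                       approach1 = approach1_config(),
                       approach2 = approach2_config(),
                       approach3 = approach3_config(),
                       reporting_grid = seq(10, 100, by = 5),
                       coverage_range = c(20, 100)) {
  structure(list(seed = seed, crl_grid = as.numeric(crl_grid),
                 n_per_value = n_per_value, window = window,
                 approach1 = approach1, approach2 = approach2,
                 approach3 = approach3,
                 reporting_grid = as.numeric(reporting_grid),
                 coverage_range = as.numeric(coverage_range)),
            class = "run_config")
}

#' Write a run configuration to JSON
#'
#' @param cfg A [run_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass_recursive(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration written by [write_config()]
#'
#' @param path JSON path.
#' @return A [run_config()]; `read_config(write_config(cfg))` reproduces `cfg`.
#' @export
read_config <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(seed = l$seed, crl_grid = l$crl_grid,
             n_per_value = l$n_per_value,
             window = truncation_window(l$window$ga_low, l$window$ga_high),
             approach1 = approach1_config(l$approach1$augment_days,
                                          l$approach1$n_per_day,
                                          l$approach1$restrict_crl,
                                          l$approach1$sensitivity_cutoffs),
             approach2 = approach2_config(l$approach2$augment_days_low,
                                          l$approach2$augment_days_high,
                                          l$approach2$n_per_day),
             approach3 = approach3_config(l$approach3$ga_eval_days,
                                          l$approach3$levels,
                                          l$approach3$sd_max_degree),
             reporting_grid = l$reporting_grid,
             coverage_range = l$coverage_range)
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}
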