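# End-to-end driver: simulate from the reference dating equation, validate
# the modelling pipeline on the untruncated data, truncate, run the three
# truncation-handling approaches and write every comparison artifact.

#' Run the full truncation simulation study
#'
#' Executes the complete pipeline: simulate GA from the reference dating
#' equation over the CRL grid; refit a dating model to the untruncated data as
#' a validation of the simulation and of the FP machinery; truncate GA to the
#' study window; run the three truncation-handling approaches; and produce
#' comparison tables, coverage counts, agreement summaries and the lower-
#' cutoff sensitivity table. When `outdir` is given, all artifacts are written
#' as CSV/JSON together with the resolved configuration and its MD5 hash.
#'
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @param seed Master integer seed; overrides `config$seed`.
#' @param config A [run_config()].
#' @param reference The reference `dating_model` simulated from (default
#'   [verburg_equation()]).
#' @param verbose Log progress to `stderr`?
#' @return (Invisibly) a list with the simulated and truncated data, the
#'   validation fit and its comparison table, the three fitted dating models,
#'   their comparison tables, coverage and agreement summaries, the
#'   sensitivity table and the resolved config.
#' @export
run_truncation_study <- function(outdir = NULL, seed = NULL,
                                 config = run_config(),
                                 reference = verburg_equation(),
                                 verbose = TRUE) {
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating %d x %d observations from the reference dating equation",
      length(config$crl_grid), config$n_per_value)
  sim <- simulate_from_dating(reference, config$crl_grid, config$n_per_value,
                              seed = seed)

  say("validation: refitting a dating model to the untruncated data")
  validation_fit <- fit_dating_model(sim)
  validation_table <- compare_to_reference(validation_fit, reference,
                                           crl_grid = seq(5, 100, by = 5))
  validation_agreement <- agreement_summary(validation_table, c(5, 100),
                                            centile = "median")

  say("truncating GA to [%g, %g) weeks", config$window$ga_low,
      config$window$ga_high)
  truncated <- truncate_ga(sim, config$window)

  say("approach 1: low-end augmentation, restriction, extrapolation")
  a1 <- run_approach1(truncated, config$approach1, seed = seed + 1L,
                      window = config$window)
  say("approach 2: two-sided augmentation")
  a2 <- run_approach2(truncated, config$approach2, seed = seed + 2L,
                      window = config$window)
  say("approach 3: axis interchange of the size chart")
  a3 <- run_approach3(truncated, config$approach3)

  models <- list(approach1 = a1, approach2 = a2, approach3 = a3)
  tables <- lapply(models, compare_to_reference, ref = reference,
                   crl_grid = config$reporting_grid)
  # goodness-of-fit coverage is counted on each approach's own fitting set
  # (augmented and/or restricted), the set its centiles were estimated from
  coverage <- lapply(models, function(m)
    coverage_counts(m, attr(m, "approach")$data,
                    crl_range = config$coverage_range))
  agreement <- list(
    approach1 = agreement_summary(tables$approach1, c(20, 100), "median"),
    approach2 = agreement_summary(tables$approach2, c(15, 85), "median"),
    approach3 = agreement_summary(tables$approach3, c(15, 100), "median"))

  say("sensitivity analysis over lower CRL cutoffs")
  sensitivity <- sensitivity_lower_cutoff(truncated, config$approach1,
                                          reference, seed = seed + 1L)

  result <- list(config = config, simulated = sim, truncated = truncated,
                 validation_fit = validation_fit,
                 validation_table = validation_table,
                 validation_agreement = validation_agreement,
                 models = models, tables = tables, coverage = coverage,
                 agreement = agreement, sensitivity = sensitivity)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_config(config, p("config.json"))
    hash <- unname(tools::md5sum(p("config.json")))
    write_observations(sim, p("simulated.csv"), p("simulated_metadata.json"))
    write_observations(truncated, p("truncated.csv"))
    write_model_json(validation_fit, p("validation_model.json"))
    write_table_csv(validation_table, p("validation_table.csv"), hash, seed)
    for (nm in names(models)) {
      write_model_json(models[[nm]], p(paste0(nm, "_model.json")))
      write_table_csv(tables[[nm]], p(paste0(nm, "_table.csv")), hash, seed)
    }
    summaries <- list(config_md5 = hash, seed = seed,
                      validation = validation_agreement,
                      agreement = agreement,
                      coverage = lapply(coverage, unclass),
                      sensitivity = sensitivity)
    jsonlite::write_json(summaries, p("summaries.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    utils::write.csv(sensitivity, p("sensitivity.csv"), row.names = FALSE)
    say("artifacts written to %s (config md5 %s)", outdir, hash)
  }
  invisible(result)
}

# CSV with a config-hash/seed comment header so every artifact is traceable
write_table_csv <- function(table, path, config_md5, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5=%s seed=%s", config_md5, seed), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' Read a comparison table CSV written by the study driver
#'
#' @param path CSV path (a `#`-prefixed provenance comment is skipped).
#' @return The comparison table as a data frame.
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  class(df) <- c("comparison_table", "data.frame")
  df
}
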