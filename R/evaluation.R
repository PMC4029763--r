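# Comparison tables, tail-coverage counts and agreement summaries between a
# fitted dating model and a reference dating equation.

#' Compare a dating model with a reference equation on a CRL grid
#'
#' Evaluates the 3rd, 50th and 97th GA centiles from both sources at each grid
#' point and reports differences in days with the convention
#' `diff = (reference - fit) * 7` (positive when the reference exceeds the
#' fit).
#'
#' @param model A fitted `dating_model`.
#' @param ref A reference `dating_model` (e.g. [verburg_equation()]).
#' @param crl_grid CRL values in mm; default 10 to 100 by 5, the usual
#'   reporting grid.
#' @param levels Centile levels, default `c(0.03, 0.5, 0.97)`.
#' @return A data frame of class `comparison_table` with columns `crl_mm`,
#'   `ref_c3`, `ref_c50`, `ref_c97`, `fit_c3`, `fit_c50`, `fit_c97` (GA in
#'   weeks, unrounded) and `diff_c3`, `diff_c50`, `diff_c97` (days), plus a
#'   logical column `extrapolated` marking grid points beyond the fitted
#'   model's CRL range.
#' @export
compare_to_reference <- function(model, ref, crl_grid = seq(10, 100, by = 5),
                                 levels = c(0.03, 0.5, 0.97)) {
  if (!inherits(model, "dating_model") || !inherits(ref, "dating_model"))
    cd_stop("model and ref must be dating models", "invalid_input")
  crl_grid <- as.numeric(crl_grid)
  if (any(!is.finite(crl_grid)) || any(crl_grid <= 0))
    cd_stop("crl_grid values must be finite and > 0", "invalid_input")
  cent <- function(m, l) as.numeric(predict_centile(m, crl_grid, level = l))
  out <- data.frame(
    crl_mm = crl_grid,
    ref_c3 = cent(ref, levels[1]), ref_c50 = cent(ref, levels[2]),
    ref_c97 = cent(ref, levels[3]),
    fit_c3 = cent(model, levels[1]), fit_c50 = cent(model, levels[2]),
    fit_c97 = cent(model, levels[3]))
  out$diff_c3 <- (out$ref_c3 - out$fit_c3) * 7
  out$diff_c50 <- (out$ref_c50 - out$fit_c50) * 7
  out$diff_c97 <- (out$ref_c97 - out$fit_c97) * 7
  out$extrapolated <- attr(predict_centile(model, crl_grid), "extrapolated")
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, digits_weeks = 2, digits_days = 2, ...) {
  d <- as.data.frame(x)
  wk <- c("ref_c3", "ref_c50", "ref_c97", "fit_c3", "fit_c50", "fit_c97")
  d[wk] <- lapply(d[wk], round, digits_weeks)
  dy <- c("diff_c3", "diff_c50", "diff_c97")
  d[dy] <- lapply(d[dy], round, digits_days)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Count observations outside the outer centiles of a dating model
#'
#' The standard goodness-of-fit check for a centile model: within a CRL range,
#' count observations whose GA lies below the model's 3rd centile or above its
#' 97th centile at their CRL.
#'
#' @param model A `dating_model`.
#' @param obs An [observation_set()].
#' @param crl_range CRL window in mm (inclusive), default c(20, 100).
#' @param levels Outer centile levels, default `c(0.03, 0.97)`.
#' @return A list of class `coverage_summary`: `n_below_3rd`, `n_above_97th`,
#'   `n_total`, `pct_below`, `pct_above`, `crl_range`.
#' @export
coverage_counts <- function(model, obs, crl_range = c(20, 100),
                            levels = c(0.03, 0.97)) {
  keep <- obs$crl_mm >= crl_range[1] & obs$crl_mm <= crl_range[2]
  if (!any(keep))
    cd_stop("no observations within the CRL range", "insufficient_data")
  crl <- obs$crl_mm[keep]; ga <- obs$ga_weeks[keep]
  lo <- as.numeric(predict_centile(model, crl, level = levels[1]))
  hi <- as.numeric(predict_centile(model, crl, level = levels[2]))
  n <- length(crl)
  below <- sum(ga < lo); above <- sum(ga > hi)
  structure(list(n_below_3rd = below, n_above_97th = above, n_total = n,
                 pct_below = 100 * below / n, pct_above = 100 * above / n,
                 crl_range = as.numeric(crl_range)),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Coverage over CRL %g-%g mm (n = %d):\n", x$crl_range[1],
              x$crl_range[2], x$n_total))
  cat(sprintf("  below 3rd centile: %d/%d (%.1f%%)\n", x$n_below_3rd,
              x$n_total, x$pct_below))
  cat(sprintf("  above 97th centile: %d/%d (%.1f%%)\n", x$n_above_97th,
              x$n_total, x$pct_above))
  invisible(x)
}

#' Summarise a difference column of a comparison table
#'
#' @param table A [compare_to_reference()] table.
#' @param crl_window CRL window in mm (inclusive) over which to summarise.
#' @param centile `"median"` (alias `"c50"`), `"c3"` or `"c97"`.
#' @return A list: `max_abs_diff_days`, `mean_diff_days`, `n` (grid points
#'   used).
#' @export
agreement_summary <- function(table, crl_window,
                              centile = c("median", "c3", "c50", "c97")) {
  centile <- match.arg(centile)
  col <- switch(centile, median = "diff_c50", c50 = "diff_c50",
                c3 = "diff_c3", c97 = "diff_c97")
  keep <- table$crl_mm >= crl_window[1] & table$crl_mm <= crl_window[2]
  if (!any(keep))
    cd_stop("the CRL window contains no grid points", "invalid_input")
  d <- table[[col]][keep]
  list(max_abs_diff_days = max(abs(d)), mean_diff_days = mean(d),
       n = sum(keep))
}
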