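#' Percentage bookkeeping for selection and split reports
#'
#' `selection_fraction()` reports the share of quality-passing features a
#' sparse model retained, as a percentage rounded to two decimals (the
#' convention used throughout the package's reports, e.g. 14 of 237 ->
#' 5.91). `fraction_pct()` is the general helper with a configurable number
#' of digits, used for cohort summary tables (e.g. 111 of 130 -> 85.4 at one
#' digit, 30 of 130 -> 23 at zero digits).
#'
#' @param n_selected number of retained features.
#' @param n_total number of features entering selection.
#' @param numerator,denominator counts for the general helper.
#' @param digits decimal places to round the percentage to.
#' @return a bare numeric percentage (already multiplied by 100).
#' @export
selection_fraction <- function(n_selected, n_total) {
  fraction_pct(n_selected, n_total, digits = 2)
}

#' @rdname selection_fraction
#' @export
fraction_pct <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) {
    abort("denominator must be positive", class = "polyomics_error_value")
  }
  round(100 * numerator / denominator, digits)
}
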