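# internal condition helpers: every package error carries class "cmspa_error"
# plus a specific subclass so callers can branch on failure kind.
abort_cmspa <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cmspa_error"), call = call))
}

warn_cmspa <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cmspa_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Roman-numeral grade labels
#'
#' The set pair analysis model used here is an m-element model: one identity
#' grade, m - 2 discrepancy grades and one contrary grade. Grades are labelled
#' with roman numerals I (best) through the m-th numeral (worst).
#'
#' @param m number of grades, an integer >= 3 (the case-study scheme uses 5).
#' @return character vector of grade labels, ordered best to worst.
#' @examples
#' grade_labels()     # "I" "II" "III" "IV" "V"
#' grade_labels(3)
#' @export
grade_labels <- function(m = 5) {
  if (!is.numeric(m) || length(m) != 1 || m < 3 || m != round(m))
    abort_cmspa("'m' must be a single integer >= 3", "cmspa_invalid_input")
  as.character(utils::as.roman(seq_len(m)))
}
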