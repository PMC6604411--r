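#' Constant-weight connection degree
#'
#' The total connection degree of a patient under scalar index weights:
#' component g is the weight-sum over the indices assigned grade g,
#' \eqn{\varphi_g = \sum_k \omega_k \, e_{kg}}, where \eqn{e_{kg}} is the
#' one-hot evaluation matrix. When the weights sum to 1 the components do
#' too (mass conservation across grades).
#'
#' @param evals an [build_evaluation_matrix()] result (indices x grades).
#' @param weights named numeric weight vector covering every row of `evals`.
#' @return named numeric vector over grades, class `connection_degree`.
#' @examples
#' ev <- matrix(c(1, 0, 0, 1, 0, 0), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("K1", "K2"), c("I", "II", "III")))
#' connection_degree(ev, c(K1 = 0.6, K2 = 0.4))
#' @export
connection_degree <- function(evals, weights) {
  if (!is.matrix(evals))
    abort_cmspa("'evals' must be a matrix", "cmspa_invalid_input")
  ids <- rownames(evals)
  if (is.null(names(weights)) || length(setdiff(ids, names(weights))))
    abort_cmspa("'weights' must be named and cover every evaluation row",
                "cmspa_invalid_input")
  if (any(weights < 0))
    abort_cmspa("weights must be non-negative", "cmspa_invalid_input")
  w <- as.numeric(weights[ids])
  cd <- as.numeric(t(unclass(evals)) %*% w)
  structure(stats::setNames(cd, colnames(evals)), class = "connection_degree")
}

#' @export
print.connection_degree <- function(x, digits = 4, ...) {
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Maximal connection degree principle
#'
#' The assessed grade is the one with the largest connection-degree
#' component. Ties are broken toward the better (lower-ordinal) grade and a
#' diagnostic warning of class `cmspa_tie` is emitted, since a tied verdict
#' deserves scrutiny.
#'
#' @param cd a [connection_degree()] (or any named numeric over grades).
#' @return the winning grade label.
#' @export
max_connection_grade <- function(cd) {
  v <- as.numeric(cd)
  if (length(v) < 2 || is.null(names(cd)))
    abort_cmspa("'cd' must be a named vector over at least 2 grades",
                "cmspa_invalid_input")
  top <- which(v == max(v))
  if (length(top) > 1)
    warn_cmspa(sprintf("connection degree tied between grades %s; choosing %s",
                       paste(names(cd)[top], collapse = ", "), names(cd)[top[1]]),
               "cmspa_tie")
  names(cd)[top[1]]
}
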