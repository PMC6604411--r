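#' Grading criterion for a single clinical index
#'
#' Maps one clinical index (wound area, pain, exudates colour, ...) to the
#' five severity grades I (best) .. V (worst). Three kinds are supported:
#'
#' * `"range"` — continuous numeric ranges. Printed range boundaries may
#'   repeat or leave cosmetic gaps ("1-4" followed by "4-9", or "21-40" after
#'   "0-20"); the effective intervals are chained lower-exclusive /
#'   upper-inclusive, with the lowest interval closed at its lower endpoint,
#'   so every value of the domain falls in exactly one grade.
#' * `"integer"` — integer ranges as printed ("0-4", "5-8", ...). Gaps
#'   between consecutive integer ranges are closed downward: a non-integer
#'   value falling in a printed gap takes the grade of the range below it.
#' * `"categorical"` — five distinct labels, one per grade.
#'
#' Grades need not be in ascending numeric order: an index where large values
#' are good (e.g. new-tissue area, grade I = "81-100") simply lists its
#' ranges per grade and the classifier orders them internally.
#'
#' @param index_id index identifier, e.g. `"K1"`.
#' @param kind `"range"`, `"integer"` or `"categorical"`.
#' @param grades character vector, one entry per grade in grade order
#'   I..V: range tokens (`"0"`, `"1-4"`, `">16"`, `"0.5-1.5"`) for numeric
#'   kinds, labels for categorical.
#' @param units free-text units (cm^2, %, VAS, ...).
#' @param labels grade labels; defaults to I..V.
#' @return an object of class `index_criterion`.
#' @examples
#' index_criterion("K1", "range", c("0", "1-4", "4-9", "9-16", ">16"), "cm^2")
#' index_criterion("K3", "categorical",
#'                 c("Transparent", "Red", "Yellow", "Green", "Black"))
#' @export
index_criterion <- function(index_id, kind = c("range", "integer", "categorical"),
                            grades, units = "",
                            labels = grade_labels(length(grades))) {
  kind <- match.arg(kind)
  if (!is.character(grades) || length(grades) < 3)
    abort_cmspa("'grades' must be a character vector with one spec per grade (>= 3)",
                "cmspa_invalid_input")
  if (length(labels) != length(grades))
    abort_cmspa("'labels' and 'grades' lengths differ", "cmspa_invalid_input")
  cr <- structure(list(index_id = index_id, kind = kind, units = units,
                       grades = stats::setNames(grades, labels)),
                  class = "index_criterion")
  if (kind == "categorical") {
    if (anyDuplicated(grades))
      abort_cmspa(sprintf("%s: categorical grade labels must be distinct", index_id),
                  "cmspa_invalid_input")
  } else {
    cr$bounds <- effective_bounds(cr)  # also validates coverage
  }
  cr
}

#' @export
print.index_criterion <- function(x, ...) {
  cat(sprintf("<criterion %s> kind=%s%s\n", x$index_id, x$kind,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  for (g in names(x$grades)) cat(sprintf("  %-4s %s\n", g, x$grades[[g]]))
  invisible(x)
}

# "0" -> c(0, 0); "1-4" -> c(1, 4); ">16" -> c(16, Inf)
parse_range_token <- function(token, index_id = "") {
  token <- trimws(token)
  if (grepl("^>", token)) {
    lo <- suppressWarnings(as.numeric(sub("^>", "", token)))
    hi <- Inf
  } else if (grepl("-", token, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(strsplit(token, "-", fixed = TRUE)[[1]]))
    if (length(parts) != 2) parts <- c(NA_real_, NA_real_)
    lo <- parts[1]; hi <- parts[2]
  } else {
    lo <- hi <- suppressWarnings(as.numeric(token))
  }
  if (is.na(lo) || is.na(hi) || lo > hi)
    abort_cmspa(sprintf("%s: cannot parse range token '%s'", index_id, token),
                "cmspa_invalid_input")
  c(lo = lo, hi = hi)
}

# Effective classification intervals for numeric criteria, in ascending
# numeric order. Returns a data.frame: grade, lo, hi, lo_inc, hi_inc.
effective_bounds <- function(criterion) {
  printed <- t(vapply(criterion$grades, parse_range_token,
                      numeric(2), index_id = criterion$index_id))
  ord <- order(printed[, "lo"])
  printed <- printed[ord, , drop = FALSE]
  labels <- names(criterion$grades)[ord]
  m <- nrow(printed)
  lo <- hi <- numeric(m)
  lo_inc <- hi_inc <- logical(m)

  if (criterion$kind == "range") {
    # chain: first interval closed below, each next (prev_hi, printed_hi]
    hi <- printed[, "hi"]
    hi_inc <- is.finite(hi)
    lo[1] <- printed[1, "lo"]; lo_inc[1] <- TRUE
    if (m > 1) {
      lo[-1] <- hi[-m]
      lo_inc[-1] <- FALSE
    }
  } else {  # integer ranges with downward gap closure
    for (p in seq_len(m)) {
      if (p == 1) { lo[p] <- printed[p, "lo"]; lo_inc[p] <- TRUE }
      else { lo[p] <- hi[p - 1]; lo_inc[p] <- !hi_inc[p - 1] }
      if (p < m) {
        if (is.infinite(printed[p + 1, "hi"])) {
          # next grade is open-ended ">x": this one keeps its printed top
          hi[p] <- printed[p + 1, "lo"]; hi_inc[p] <- TRUE
        } else {
          hi[p] <- printed[p + 1, "lo"]; hi_inc[p] <- FALSE
        }
      } else {
        hi[p] <- printed[p, "hi"]; hi_inc[p] <- is.finite(printed[p, "hi"])
      }
    }
  }
  if (any(lo[-1] != hi[-m]))
    abort_cmspa(sprintf("%s: grade ranges leave an uncoverable gap",
                        criterion$index_id), "cmspa_invalid_input")
  data.frame(grade = labels, lo = lo, hi = hi, lo_inc = lo_inc, hi_inc = hi_inc,
             stringsAsFactors = FALSE)
}

#' Classify one index value into a severity grade
#'
#' @param criterion an [index_criterion()].
#' @param value a numeric value (for range/integer criteria) or a category
#'   label (for categorical criteria).
#' @return the grade label (e.g. `"I"`).
#' @examples
#' k1 <- index_criterion("K1", "range", c("0", "1-4", "4-9", "9-16", ">16"))
#' classify_value(k1, 35)  # "V"
#' @export
classify_value <- function(criterion, value) {
  stopifnot(inherits(criterion, "index_criterion"))
  if (criterion$kind == "categorical") {
    if (!is.character(value) || length(value) != 1)
      abort_cmspa(sprintf("%s expects a category label", criterion$index_id),
                  "cmspa_invalid_category")
    hit <- match(trimws(value), trimws(criterion$grades))
    if (is.na(hit))
      abort_cmspa(sprintf("%s: unknown category '%s'", criterion$index_id, value),
                  "cmspa_invalid_category")
    return(names(criterion$grades)[hit])
  }
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value))
    abort_cmspa(sprintf("%s expects a finite numeric value", criterion$index_id),
                "cmspa_invalid_input")
  b <- criterion$bounds
  ok <- (value > b$lo | (b$lo_inc & value == b$lo)) &
        (value < b$hi | (b$hi_inc & value == b$hi))
  if (!any(ok))
    abort_cmspa(sprintf("%s: value %s lies outside the graded domain",
                        criterion$index_id, format(value)),
                "cmspa_out_of_domain")
  b$grade[which(ok)[1]]
}

#' Grading scheme: one criterion per clinical index
#'
#' @param criteria a list of [index_criterion()] objects with unique ids.
#' @return object of class `grading_scheme`; indexable by id.
#' @export
grading_scheme <- function(criteria) {
  if (!is.list(criteria) || length(criteria) == 0 ||
      !all(vapply(criteria, inherits, logical(1), "index_criterion")))
    abort_cmspa("'criteria' must be a non-empty list of index_criterion objects",
                "cmspa_invalid_input")
  ids <- vapply(criteria, `[[`, character(1), "index_id")
  if (anyDuplicated(ids))
    abort_cmspa("duplicate index ids in grading scheme", "cmspa_invalid_input")
  structure(stats::setNames(criteria, ids), class = "grading_scheme")
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat(sprintf("<grading scheme> %d indices: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Patient record of index values
#'
#' @param patient_id patient label.
#' @param values named list/vector mapping index ids to numeric values or
#'   category labels.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(patient_id, values) {
  values <- as.list(values)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    abort_cmspa("'values' must be named by index id", "cmspa_invalid_input")
  structure(list(patient_id = patient_id, values = values),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient %s> %s\n", x$patient_id,
              paste(names(x$values), unlist(lapply(x$values, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Build the one-hot evaluation matrix of a patient
#'
#' Classifies every index value of the patient under the grading scheme. Row
#' k of the result is the one-hot indicator of the grade of index k: the set
#' pair analysis coherence / discrepancy / contrary degrees of a single index
#' are 1 for the grade its value falls in and 0 elsewhere.
#'
#' @param scheme a [grading_scheme()].
#' @param patient a [patient_record()] covering all scheme indices.
#' @return an integer matrix (indices x grades, entries 0/1) of class
#'   `evaluation_matrix`; every row sums to 1.
#' @export
build_evaluation_matrix <- function(scheme, patient) {
  stopifnot(inherits(scheme, "grading_scheme"), inherits(patient, "patient_record"))
  missing_ids <- setdiff(names(scheme), names(patient$values))
  if (length(missing_ids))
    abort_cmspa(sprintf("patient '%s' lacks values for: %s", patient$patient_id,
                        paste(missing_ids, collapse = ", ")),
                "cmspa_invalid_input")
  grades <- names(scheme[[1]]$grades)
  ev <- matrix(0L, nrow = length(scheme), ncol = length(grades),
               dimnames = list(names(scheme), grades))
  for (id in names(scheme)) {
    g <- tryCatch(classify_value(scheme[[id]], patient$values[[id]]),
                  cmspa_error = function(e) {
                    abort_cmspa(sprintf("index %s of patient '%s': %s", id,
                                        patient$patient_id, conditionMessage(e)),
                                class(e)[1])
                  })
    ev[id, g] <- 1L
  }
  structure(ev, class = c("evaluation_matrix", class(ev)))
}

#' @export
print.evaluation_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}
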