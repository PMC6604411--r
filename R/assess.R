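#' Run a full efficacy assessment
#'
#' End-to-end pipeline over a cohort of patients. In `"cm-spa"` mode the
#' expert panel is condensed to cloud weights, each patient's evaluation
#' matrix is aggregated into a cloud connection degree, and the 3En rule plus
#' the maximal connection degree principle produce a verdict per patient. In
#' `"ahp-spa"` mode a scalar weight vector (e.g. from [synthesize()] or a
#' reference table) yields classical connection degrees and max-grade
#' verdicts.
#'
#' @param panel a [judgment_panel()] (required for mode `"cm-spa"`).
#' @param scheme a [grading_scheme()].
#' @param patients list of [patient_record()] objects (may be empty).
#' @param mode `"cm-spa"` or `"ahp-spa"`.
#' @param weights named scalar weight vector, required for mode `"ahp-spa"`.
#' @return list of class `assessment_result` with elements `mode`, `weights`
#'   (cloud weight set or scalar vector), `evaluations` (per-patient
#'   evaluation matrices), `ccd` / `cd` (per-patient tables) and `verdicts`.
#' @examples
#' bundle <- load_fixture_bundle()
#' res <- run_assessment(bundle$panel, bundle$scheme, bundle$patients)
#' res$verdicts[["Cheng-ming Luan"]]
#' @export
run_assessment <- function(panel = NULL, scheme, patients,
                           mode = c("cm-spa", "ahp-spa"), weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "grading_scheme"))
  names(patients) <- vapply(patients, `[[`, character(1), "patient_id")

  problems <- character(0)
  evals <- list()
  for (p in patients) {
    ev <- tryCatch(build_evaluation_matrix(scheme, p),
                   cmspa_error = function(e) conditionMessage(e))
    if (is.character(ev)) problems <- c(problems, ev)
    else evals[[p$patient_id]] <- ev
  }
  if (length(problems))
    abort_cmspa(paste0("invalid inputs:\n  ", paste(problems, collapse = "\n  ")),
                "cmspa_invalid_input")

  if (mode == "cm-spa") {
    if (is.null(panel))
      abort_cmspa("mode 'cm-spa' needs an expert panel", "cmspa_invalid_input")
    w <- cloud_weights(panel)
    ccd <- lapply(evals, cloud_connection_degree, weights = w)
    verdicts <- lapply(ccd, interpret_ccd)
    out <- list(mode = mode, weights = w, evaluations = evals, ccd = ccd,
                verdicts = verdicts)
  } else {
    if (is.null(weights))
      abort_cmspa("mode 'ahp-spa' needs a scalar weight vector",
                  "cmspa_invalid_input")
    cd <- lapply(evals, connection_degree, weights = weights)
    verdicts <- lapply(cd, max_connection_grade)
    out <- list(mode = mode, weights = weights, evaluations = evals, cd = cd,
                verdicts = verdicts)
  }
  structure(out, class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("<assessment result> mode = %s, %d patient(s)\n", x$mode,
              length(x$evaluations)))
  for (p in names(x$verdicts)) {
    v <- x$verdicts[[p]]
    if (inherits(v, "assessment_verdict")) {
      cat(sprintf("  %s: %s\n", p, v$narrative))
    } else {
      cat(sprintf("  %s: grade %s (maximal connection degree)\n", p, v))
    }
  }
  invisible(x)
}
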