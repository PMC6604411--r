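# Embedded diabetic-ulcer case study: a 10-expert importance panel over 10
# wound indices, the 5-grade severity scheme, three treated patients, and the
# AHP reference weights. Everything is defined in code so the bundle is
# byte-identical across calls and needs no external files.

fixture_panel_scores <- function() {
  experts <- matrix(c(
    6, 10, 10, 8, 8, 9, 8, 7, 8, 5,
    10, 9, 8, 6, 8, 9, 9, 8, 7, 5,
    7, 10, 6, 5, 8, 9, 8, 5, 5, 5,
    9, 8, 9, 6, 7, 9, 9, 7, 5, 6,
    10, 10, 8, 8, 9, 8, 7, 7, 7, 6,
    8, 8, 5, 5, 5, 5, 5, 4, 4, 5,
    6, 7, 6, 6, 5, 7, 8, 8, 7, 7,
    7, 9, 8, 7, 7, 7, 8, 6, 6, 7,
    10, 7, 9, 9, 7, 9, 9, 9, 7, 7,
    7, 9, 8, 5, 8, 7, 7, 7, 5, 6), nrow = 10, byrow = TRUE,
    dimnames = list(paste0("Expert", 1:10), paste0("K", 1:10)))
  t(experts)  # canonical orientation: indices x experts
}

fixture_experts <- function() {
  data.frame(
    expert = paste0("Expert", 1:10),
    position = c("Student", "Student", "Doctor-in-charge", "Doctor-in-charge",
                 "Doctor-in-charge", "Associate Professor", "Associate Professor",
                 "Professor", "Professor", "Professor"),
    education = c("Bachelor", "Master", "Master", "Master", "PhD", "Master",
                  "PhD", "PhD", "PhD", "PhD"),
    years = c(2, 4, 10, 10, 15, 22, 25, 29, 35, 40),
    stringsAsFactors = FALSE)
}

fixture_scheme <- function() {
  grading_scheme(list(
    index_criterion("K1", "range", c("0", "1-4", "4-9", "9-16", ">16"),
                    units = "cm^2"),
    index_criterion("K2", "range", c("0-1", "1-2", "2-3", "3-4", ">4"),
                    units = "cm"),
    index_criterion("K3", "categorical",
                    c("Transparent", "Red", "Yellow", "Green", "Black")),
    index_criterion("K4", "integer", c("0-4", "5-8", "9-12", "13-16", ">16"),
                    units = "layers of gauze wetted"),
    index_criterion("K5", "range", c("0-20", "21-40", "41-60", "61-80", "81-100"),
                    units = "%"),
    index_criterion("K6", "categorical",
                    c("Bright red", "Red", "Light red", "Pink", "Pale")),
    index_criterion("K7", "range", c("81-100", "61-80", "41-60", "21-40", "0-20"),
                    units = "%"),
    index_criterion("K8", "categorical",
                    c("Normal", "Slightly hot", "Hot", "Pretty hot",
                      "Scorching hot")),
    index_criterion("K9", "categorical",
                    c("Normal", "Reddish", "Red", "Bright red", "Dark red")),
    index_criterion("K10", "integer", c("0-2", "3-4", "5-6", "7-8", "9-10"),
                    units = "VAS")))
}

fixture_patients <- function() {
  list(
    patient_record("Cheng-ming Luan", list(
      K1 = 1, K2 = 0.5, K3 = "Transparent", K4 = 3, K5 = 0,
      K6 = "Bright red", K7 = 24, K8 = "Normal", K9 = "Normal", K10 = 3)),
    patient_record("Di-he Gu", list(
      K1 = 6, K2 = 0.3, K3 = "Transparent", K4 = 7, K5 = 0,
      K6 = "Red", K7 = 0, K8 = "Normal", K9 = "Bright red", K10 = 5)),
    patient_record("Hong-Liu", list(
      K1 = 35, K2 = 0.4, K3 = "Red", K4 = 11, K5 = 10,
      K6 = "Bright red", K7 = 42, K8 = "Slightly hot", K9 = "Red", K10 = 7)))
}

fixture_ahp_weights <- function() {
  stats::setNames(
    c(0.0658, 0.0916, 0.1163, 0.1706, 0.1996,
      0.0755, 0.0716, 0.0456, 0.1191, 0.0443),
    paste0("K", 1:10))
}

fixture_linguistic_scale <- function() {
  data.frame(
    level = c("Very important", "Important", "Middle important",
              "Unimportant", "Very unimportant"),
    lo = c(8, 6, 4, 2, 0), hi = c(10, 8, 6, 4, 2),
    stringsAsFactors = FALSE)
}

#' The embedded diabetic-ulcer case-study bundle
#'
#' Returns the full worked case study: the 10 x 10 expert importance panel
#' (with the expert roster attached), the 5-grade wound severity scheme over
#' indices K1 (wound area, cm^2) .. K10 (pain, VAS), the three treated
#' patients, the AHP reference weight vector for the comparison arm, and the
#' 10-point linguistic judgment scale. The bundle is built in code and is
#' identical on every call.
#'
#' @return list of class `fixture_bundle` with elements `panel`
#'   ([judgment_panel()]), `experts` (data.frame), `scheme`
#'   ([grading_scheme()]), `patients` (list of [patient_record()]),
#'   `ahp_weights` (named numeric) and `linguistic_scale` (data.frame).
#' @examples
#' bundle <- load_fixture_bundle()
#' cloud_weights(bundle$panel)
#' @export
load_fixture_bundle <- function() {
  structure(list(
    panel = judgment_panel(fixture_panel_scores(), fixture_experts()),
    experts = fixture_experts(),
    scheme = fixture_scheme(),
    patients = fixture_patients(),
    ahp_weights = fixture_ahp_weights(),
    linguistic_scale = fixture_linguistic_scale()),
    class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<case-study bundle> %d indices, %d experts, %d patients\n",
              nrow(x$panel$scores), ncol(x$panel$scores), length(x$patients)))
  invisible(x)
}
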