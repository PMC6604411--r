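#' Expert judgment panel
#'
#' Holds the raw importance scores x_kl given by expert l to index k. Scores
#' live on the 10-point linguistic scale: (0, 2] very unimportant up to
#' (8, 10] very important. Expert metadata (position, education, years of
#' experience) may be attached; all experts are weighted equally.
#'
#' @param scores numeric matrix, indices as rows, experts as columns, all
#'   entries in (0, 10].
#' @param experts optional data.frame of per-expert metadata (one row per
#'   column of `scores`).
#' @return object of class `judgment_panel` with elements `scores`, `experts`.
#' @export
judgment_panel <- function(scores, experts = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    abort_cmspa("'scores' must be a numeric matrix (indices x experts)",
                "cmspa_invalid_input")
  if (any(!is.finite(scores)) || any(scores <= 0) || any(scores > 10))
    abort_cmspa("scores must be finite and in (0, 10]", "cmspa_invalid_panel")
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("K", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("Expert", seq_len(ncol(scores)))
  if (!is.null(experts) && nrow(experts) != ncol(scores))
    abort_cmspa("'experts' must have one row per expert column",
                "cmspa_invalid_input")
  structure(list(scores = scores, experts = experts), class = "judgment_panel")
}

#' @export
print.judgment_panel <- function(x, ...) {
  cat(sprintf("<judgment panel> %d indices x %d experts\n",
              nrow(x$scores), ncol(x$scores)))
  print(x$scores)
  invisible(x)
}

#' Normalize an expert panel column-wise
#'
#' Each expert's scores are divided by that expert's total over all indices,
#' \eqn{X_{kl} = x_{kl} / \sum_k x_{kl}}, so every expert distributes one
#' unit of importance mass over the indices.
#'
#' @param panel a [judgment_panel()] (or a bare scores matrix).
#' @return numeric matrix of the same shape whose columns each sum to 1,
#'   with class `normalized_panel`.
#' @export
normalize_panel <- function(panel) {
  scores <- if (inherits(panel, "judgment_panel")) panel$scores else panel
  if (!is.matrix(scores) || !is.numeric(scores))
    abort_cmspa("'panel' must be a judgment_panel or numeric matrix",
                "cmspa_invalid_input")
  tot <- colSums(scores)
  if (any(!is.finite(tot)) || any(tot <= 0))
    abort_cmspa("every expert column must have a positive score sum",
                "cmspa_invalid_panel")
  x <- sweep(scores, 2, tot, "/")
  structure(x, class = c("normalized_panel", class(x)))
}

#' Cloud weights of the assessment indices
#'
#' The central step of the cloud-model arm: after per-expert normalization
#' each index row of the panel is a sample of relative-importance values, and
#' the backward cloud generator condenses it to a cloud weight
#' \eqn{\omega(C)_k = (Ex_k, En_k, He_k)}. Ex is the consensus weight (the
#' Ex values sum to 1 across indices), En measures the between-expert spread
#' and He the instability of that spread. Any index whose cloud degenerates
#' to fog (confusion degree >= 1) triggers a `cmspa_fog` warning: the
#' experts should be asked again.
#'
#' @param panel a [judgment_panel()] with at least 2 experts.
#' @return a data.frame (index, ex, en, he) of class `cloud_weight_set`; the
#'   per-index [cloud_descriptor()] objects are in attribute `"descriptors"`.
#' @seealso [backward_cloud()], [cloud_connection_degree()]
#' @export
cloud_weights <- function(panel) {
  x <- normalize_panel(panel)
  if (ncol(x) < 2)
    abort_cmspa("cloud weights need at least 2 experts", "cmspa_invalid_input")
  descs <- lapply(seq_len(nrow(x)), function(k) backward_cloud(x[k, ]))
  names(descs) <- rownames(x)
  for (k in names(descs)) {
    d <- descs[[k]]
    if (d$en > 0 && is_fog(d))
      warn_cmspa(sprintf("index %s: confusion degree %.3f >= 1, cloud degenerates to fog",
                         k, confusion_degree(d)), "cmspa_fog")
  }
  out <- data.frame(index = names(descs),
                    ex = vapply(descs, `[[`, numeric(1), "ex"),
                    en = vapply(descs, `[[`, numeric(1), "en"),
                    he = vapply(descs, `[[`, numeric(1), "he"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("cloud_weight_set", "data.frame"),
            descriptors = descs)
}

#' @export
print.cloud_weight_set <- function(x, digits = 5, ...) {
  cat("<cloud weights>\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

cloud_weight_descriptors <- function(weights) {
  d <- attr(weights, "descriptors")
  if (!is.null(d)) return(d)
  stats::setNames(lapply(seq_len(nrow(weights)), function(i)
    cloud_descriptor(weights$ex[i], weights$en[i], weights$he[i])),
    weights$index)
}

#' Cloud connection degree of a patient
#'
#' Aggregates the cloud weights of the indices assigned to each grade: for
#' grade g the Ex values add and the En / He values add in quadrature (see
#' [aggregate_clouds()]). Grades supported by no index get the crisp zero
#' cloud (0, 0, 0).
#'
#' @param evals an [build_evaluation_matrix()] result.
#' @param weights a [cloud_weights()] result covering every row of `evals`.
#' @return data.frame (grade, ex, en, he) of class `cloud_connection_degree`;
#'   per-grade descriptors in attribute `"descriptors"`.
#' @export
cloud_connection_degree <- function(evals, weights) {
  if (!is.matrix(evals))
    abort_cmspa("'evals' must be an evaluation matrix", "cmspa_invalid_input")
  descs <- cloud_weight_descriptors(weights)
  missing_ids <- setdiff(rownames(evals), names(descs))
  if (length(missing_ids))
    abort_cmspa(sprintf("cloud weights missing for: %s",
                        paste(missing_ids, collapse = ", ")),
                "cmspa_invalid_input")
  grades <- colnames(evals)
  per_grade <- lapply(grades, function(g) {
    members <- rownames(evals)[evals[, g] == 1]
    if (length(members) == 0) cloud_descriptor(0, 0, 0)
    else aggregate_clouds(descs[members])
  })
  names(per_grade) <- grades
  out <- data.frame(grade = grades,
                    ex = vapply(per_grade, `[[`, numeric(1), "ex"),
                    en = vapply(per_grade, `[[`, numeric(1), "en"),
                    he = vapply(per_grade, `[[`, numeric(1), "he"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("cloud_connection_degree", "data.frame"),
            descriptors = per_grade)
}

#' @export
print.cloud_connection_degree <- function(x, digits = 4, ...) {
  cat("<cloud connection degree>\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

ccd_descriptors <- function(ccd) {
  d <- attr(ccd, "descriptors")
  if (!is.null(d)) return(d)
  stats::setNames(lapply(seq_len(nrow(ccd)), function(i)
    cloud_descriptor(ccd$ex[i], ccd$en[i], ccd$he[i])), ccd$grade)
}

#' Interpret a cloud connection degree
#'
#' Applies the maximal connection degree principle on the Ex components and
#' the 3En rule on the per-grade clouds: the primary grade is the one with
#' the largest Ex; its 3En interval is compared with the intervals of every
#' other supported grade. If none intersects, the verdict is pure ("the
#' patient completely belongs to" the primary grade). Otherwise the
#' secondary grade is the one whose interval overlaps the primary's the
#' most, and the verdict is "between primary and secondary, closer to the
#' primary". Grades with the zero cloud are excluded from the analysis.
#'
#' @param ccd a [cloud_connection_degree()] with at least one nonzero grade.
#' @return object of class `assessment_verdict` with fields `primary_grade`,
#'   `secondary_grade` (or `NULL`), `intervals` (3En interval per supported
#'   grade), `overlap_lengths` (primary vs each other grade) and `narrative`.
#' @export
interpret_ccd <- function(ccd) {
  if (!inherits(ccd, "cloud_connection_degree"))
    abort_cmspa("'ccd' must be a cloud_connection_degree", "cmspa_invalid_input")
  descs <- ccd_descriptors(ccd)
  nonzero <- names(descs)[vapply(descs, function(d)
    d$ex != 0 || d$en != 0 || d$he != 0, logical(1))]
  if (length(nonzero) == 0)
    abort_cmspa("all grades carry the zero cloud; nothing to interpret",
                "cmspa_invalid_input")
  ex <- vapply(descs[nonzero], `[[`, numeric(1), "ex")
  top <- which(ex == max(ex))
  if (length(top) > 1)
    warn_cmspa(sprintf("maximal Ex tied between grades %s",
                       paste(nonzero[top], collapse = ", ")), "cmspa_tie")
  primary <- nonzero[top[1]]
  intervals <- lapply(descs[nonzero], three_en_interval)
  others <- setdiff(nonzero, primary)
  overlaps <- vapply(others, function(g)
    overlap_length(intervals[[primary]], intervals[[g]]), numeric(1))
  names(overlaps) <- if (length(others)) paste(primary, others, sep = "~")
                     else character(0)
  intersecting <- others[vapply(others, function(g)
    !is.null(interval_overlap(intervals[[primary]], intervals[[g]])), logical(1))]
  if (length(intersecting) == 0) {
    secondary <- NULL
    narrative <- sprintf(
      "The assessment completely belongs to grade %s: its 3En interval does not intersect any other grade's.",
      primary)
  } else {
    ov <- overlaps[paste(primary, intersecting, sep = "~")]
    secondary <- intersecting[which.max(ov)]
    narrative <- sprintf(
      "The assessment lies between grade %s and grade %s, closer to grade %s (their 3En intervals overlap the most, length %.4f).",
      primary, secondary, primary, max(ov))
  }
  structure(list(primary_grade = primary, secondary_grade = secondary,
                 intervals = intervals, overlap_lengths = overlaps,
                 narrative = narrative),
            class = "assessment_verdict")
}

#' @export
print.assessment_verdict <- function(x, digits = 4, ...) {
  cat("<assessment verdict>\n")
  cat(" ", x$narrative, "\n")
  for (g in names(x$intervals)) {
    iv <- x$intervals[[g]]
    cat(sprintf("  grade %-4s 3En interval [%s, %s]\n", g,
                round(iv[["lo"]], digits), round(iv[["hi"]], digits)))
  }
  invisible(x)
}
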