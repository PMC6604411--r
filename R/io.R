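# Delimited-text I/O. All tables are plain CSV with a header row; the
# canonical index order K1..K10 is preserved on write and trusted on read.

#' Read / write an expert judgment panel
#'
#' Panel files hold indices as rows and experts as columns, with the index
#' id in the first column.
#'
#' @param file path to a CSV file.
#' @return [read_judgment_panel()] returns a [judgment_panel()];
#'   `write_judgment_panel` returns the path invisibly.
#' @export
read_judgment_panel <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  judgment_panel(m)
}

#' @rdname read_judgment_panel
#' @param panel a [judgment_panel()].
#' @export
write_judgment_panel <- function(panel, file) {
  stopifnot(inherits(panel, "judgment_panel"))
  df <- data.frame(index = rownames(panel$scores), panel$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write a grading scheme
#'
#' Scheme files have columns `index`, `kind`, `units` and one column per
#' grade holding range tokens (`"0"`, `"1-4"`, `">16"`) or category labels.
#'
#' @param file path to a CSV file.
#' @return a [grading_scheme()] / the path invisibly.
#' @export
read_grading_scheme <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  grade_cols <- setdiff(names(df), c("index", "kind", "units"))
  grading_scheme(lapply(seq_len(nrow(df)), function(i)
    index_criterion(df$index[i], df$kind[i],
                    as.character(df[i, grade_cols]),
                    units = df$units[i], labels = grade_cols)))
}

#' @rdname read_grading_scheme
#' @param scheme a [grading_scheme()].
#' @export
write_grading_scheme <- function(scheme, file) {
  stopifnot(inherits(scheme, "grading_scheme"))
  grades <- names(scheme[[1]]$grades)
  rows <- lapply(scheme, function(cr)
    c(index = cr$index_id, kind = cr$kind, units = cr$units,
      stats::setNames(as.character(cr$grades), grades)))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Read / write patient records
#'
#' Patient files hold indices as rows and patients as columns (the layout of
#' a clinical index table); values are stored as text and re-typed against
#' the scheme on read, numeric where the criterion is numeric.
#'
#' @param file path to a CSV file.
#' @param scheme the [grading_scheme()] used to type values on read.
#' @return a list of [patient_record()] / the path invisibly.
#' @export
read_patient_records <- function(file, scheme) {
  stopifnot(inherits(scheme, "grading_scheme"))
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  ids <- df[[1]]
  lapply(names(df)[-1], function(p) {
    vals <- lapply(seq_along(ids), function(i) {
      v <- df[[p]][i]
      if (scheme[[ids[i]]]$kind == "categorical") v else as.numeric(v)
    })
    patient_record(p, stats::setNames(vals, ids))
  })
}

#' @rdname read_patient_records
#' @param patients a list of [patient_record()].
#' @export
write_patient_records <- function(patients, file) {
  ids <- names(patients[[1]]$values)
  df <- data.frame(index = ids, stringsAsFactors = FALSE, check.names = FALSE)
  for (p in patients)
    df[[p$patient_id]] <- vapply(p$values[ids], function(v) format(v, trim = TRUE),
                                 character(1))
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Read / write a scalar weight vector
#'
#' @param file path to a CSV with columns `index`, `weight`.
#' @return named numeric vector / the path invisibly.
#' @export
read_weight_vector <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$weight), df$index)
}

#' @rdname read_weight_vector
#' @param weights named numeric vector.
#' @export
write_weight_vector <- function(weights, file) {
  utils::write.csv(data.frame(index = names(weights),
                              weight = as.numeric(weights)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a pairwise comparison matrix
#'
#' Accepts fraction tokens such as `"1/3"` in the cells and normalizes them
#' to numeric ratios on read.
#'
#' @param file path to a CSV: first column row labels, remaining columns the
#'   comparison entries.
#' @return a validated [pairwise_matrix()].
#' @export
read_pairwise_matrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  parse_cell <- function(s) {
    s <- trimws(s)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
      parts[1] / parts[2]
    } else as.numeric(s)
  }
  m <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), parse_cell)
  dimnames(m) <- list(df[[1]], names(df)[-1])
  pairwise_matrix(m)
  m
}

#' Export an evaluation matrix, CCD table or CD table as CSV
#'
#' @param x an `evaluation_matrix`, `cloud_connection_degree`,
#'   `cloud_weight_set` or `connection_degree`.
#' @param file output path.
#' @return the path invisibly.
#' @export
write_table_csv <- function(x, file) {
  if (inherits(x, "evaluation_matrix")) {
    df <- data.frame(index = rownames(x), unclass(x), check.names = FALSE)
  } else if (inherits(x, "connection_degree")) {
    df <- data.frame(grade = names(x), value = as.numeric(x))
  } else {
    df <- as.data.frame(x)
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
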