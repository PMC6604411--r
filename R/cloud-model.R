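#' Cloud descriptor (Ex, En, He)
#'
#' A normal cloud encodes a qualitative concept by three numbers: the expected
#' value `ex` (the centre of gravity of the concept on its numeric scale), the
#' entropy `en >= 0` (joint measure of fuzziness and randomness, the spread of
#' the concept), and the hyper-entropy `he >= 0` (the dispersion of the
#' entropy itself, i.e. how much the experts disagree about the spread). The
#' degenerate descriptor with `en = 0, he = 0` is a crisp value.
#'
#' @param ex expected value (finite numeric scalar).
#' @param en entropy, a non-negative finite scalar.
#' @param he hyper-entropy, a non-negative finite scalar.
#' @return an object of class `cloud_descriptor`.
#' @seealso [backward_cloud()], [forward_cloud()], [confusion_degree()],
#'   [three_en_interval()], [aggregate_clouds()]
#' @examples
#' cloud_descriptor(5, 1, 0.1)
#' cloud_descriptor(0.3, 0, 0)  # crisp value
#' @export
cloud_descriptor <- function(ex, en, he) {
  for (v in list(ex, en, he))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort_cmspa("cloud descriptor components must be finite numeric scalars",
                  "cmspa_invalid_input")
  if (en < 0 || he < 0)
    abort_cmspa("'en' and 'he' must be non-negative", "cmspa_invalid_input")
  structure(list(ex = as.numeric(ex), en = as.numeric(en), he = as.numeric(he)),
            class = "cloud_descriptor")
}

#' @export
print.cloud_descriptor <- function(x, digits = 5, ...) {
  cat(sprintf("<cloud> Ex = %.*g, En = %.*g, He = %.*g\n",
              digits, x$ex, digits, x$en, digits, x$he))
  invisible(x)
}

#' @export
format.cloud_descriptor <- function(x, digits = 4, ...) {
  sprintf("(%s, %s, %s)", round(x$ex, digits), round(x$en, digits),
          round(x$he, digits))
}

is_cloud_descriptor <- function(x) inherits(x, "cloud_descriptor")

#' Backward cloud generator
#'
#' Estimates a cloud descriptor from a sample of realisations of a concept.
#' The estimators are
#' \deqn{Ex = \bar x, \quad
#'       En = \sqrt{\pi/2}\,\frac{1}{n}\sum_i |x_i - Ex|, \quad
#'       He = \sqrt{\,\left| s^2 - En^2 \right|\,}}
#' where \eqn{s^2} is the sample variance with denominator \eqn{n - 1}. The
#' absolute value guards the radicand: with small samples the first-order
#' absolute deviation estimate of En can exceed the variance, and a spread
#' parameter must stay real and non-negative.
#'
#' @param samples numeric vector of at least 2 finite values.
#' @return a [cloud_descriptor()].
#' @examples
#' backward_cloud(c(0, 0.2))
#' backward_cloud(rep(0.1, 10))  # zero dispersion -> crisp cloud
#' @export
backward_cloud <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 2)
    abort_cmspa("need at least 2 numeric samples", "cmspa_invalid_input")
  if (any(!is.finite(samples)))
    abort_cmspa("all samples must be finite", "cmspa_invalid_input")
  ex <- mean(samples)
  en <- sqrt(pi / 2) * mean(abs(samples - ex))
  he <- sqrt(abs(stats::var(samples) - en^2))
  cloud_descriptor(ex, en, he)
}

#' Forward cloud generator
#'
#' Draws cloud drops from a descriptor: for each drop an entropy realisation
#' `en'` is drawn from N(en, he^2), then `x ~ N(ex, en'^2)` and the membership
#' degree is `mu = exp(-(x - ex)^2 / (2 en'^2))`, recomputed per drop with
#' that drop's `en'`. A negative `en'` draw is used through its absolute value
#' (a spread cannot be negative). The crisp descriptor (en = 0, he = 0)
#' produces all drops at `x = ex` with `mu = 1`.
#'
#' @param desc a [cloud_descriptor()].
#' @param n_drops number of drops, a positive integer.
#' @param seed optional integer seed; with a seed the output is reproducible.
#' @return a data.frame of class `cloud_drops` with columns `x` and `mu`.
#' @examples
#' drops <- forward_cloud(cloud_descriptor(5, 1, 0.1), 1000, seed = 1)
#' mean(drops$x)
#' @export
forward_cloud <- function(desc, n_drops, seed = NULL) {
  stopifnot(is_cloud_descriptor(desc))
  if (!is.numeric(n_drops) || length(n_drops) != 1 || n_drops < 1 ||
      n_drops != round(n_drops))
    abort_cmspa("'n_drops' must be a positive integer", "cmspa_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  enp <- abs(stats::rnorm(n_drops, mean = desc$en, sd = desc$he))
  x <- stats::rnorm(n_drops, mean = desc$ex, sd = enp)
  mu <- ifelse(enp == 0, 1, exp(-(x - desc$ex)^2 / (2 * enp^2)))
  structure(data.frame(x = x, mu = mu),
            class = c("cloud_drops", "data.frame"))
}

#' Confusion degree of a cloud
#'
#' The ratio `3 He / En`. A value below 1 means the drops still form a
#' recognisable bell-shaped cloud; at 1 or above the cloud degenerates to
#' "fog" and the underlying concept should be re-elicited from the experts.
#' A crisp cloud (`en = 0`) has no confusion degree.
#'
#' @param desc a [cloud_descriptor()] with `en > 0`.
#' @return non-negative scalar.
#' @examples
#' confusion_degree(cloud_descriptor(5, 1, 0.1))  # 0.3
#' @export
confusion_degree <- function(desc) {
  stopifnot(is_cloud_descriptor(desc))
  if (desc$en == 0)
    abort_cmspa("confusion degree is undefined for a crisp cloud (en = 0)",
                "cmspa_undefined_confusion")
  3 * desc$he / desc$en
}

#' Is a cloud degenerate fog?
#'
#' @param desc a [cloud_descriptor()] with `en > 0`.
#' @return `TRUE` when the confusion degree is >= 1.
#' @export
is_fog <- function(desc) confusion_degree(desc) >= 1

#' Numeric interval
#'
#' @param lo,hi bounds with `lo <= hi`.
#' @return object of class `spa_interval`.
#' @export
interval <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1)
    abort_cmspa("interval bounds must be numeric scalars", "cmspa_invalid_input")
  if (lo > hi)
    abort_cmspa("interval requires lo <= hi", "cmspa_invalid_input")
  structure(c(lo = as.numeric(lo), hi = as.numeric(hi)), class = "spa_interval")
}

#' @export
print.spa_interval <- function(x, digits = 4, ...) {
  cat(sprintf("[%s, %s]\n", round(x[["lo"]], digits), round(x[["hi"]], digits)))
  invisible(x)
}

#' The 3En interval of a cloud
#'
#' About 99.7% of the drops of a normal cloud fall in
#' `[Ex - 3 En, Ex + 3 En]`; drops outside contribute negligibly to the
#' concept (the "3En rule"). This interval is what turns a cloud-valued
#' assessment into a decision interval.
#'
#' @param desc a [cloud_descriptor()].
#' @return an [interval()].
#' @examples
#' three_en_interval(cloud_descriptor(5, 1, 0.1))  # [2, 8]
#' @export
three_en_interval <- function(desc) {
  stopifnot(is_cloud_descriptor(desc))
  interval(desc$ex - 3 * desc$en, desc$ex + 3 * desc$en)
}

#' Intersection of two intervals
#'
#' @param a,b objects from [interval()].
#' @return the intersection interval, or `NULL` when the intervals are
#'   disjoint. Touching intervals intersect in a single point (length 0).
#' @seealso [overlap_length()]
#' @export
interval_overlap <- function(a, b) {
  stopifnot(inherits(a, "spa_interval"), inherits(b, "spa_interval"))
  lo <- max(a[["lo"]], b[["lo"]])
  hi <- min(a[["hi"]], b[["hi"]])
  if (lo > hi) NULL else interval(lo, hi)
}

#' Length of the intersection of two intervals
#'
#' @inheritParams interval_overlap
#' @return `max(0, min(hi) - max(lo))`; 0 for disjoint or touching intervals.
#' @export
overlap_length <- function(a, b) {
  ov <- interval_overlap(a, b)
  if (is.null(ov)) 0 else unname(ov[["hi"]] - ov[["lo"]])
}

#' Aggregate independent clouds
#'
#' Sums cloud descriptors under the independent-cloud arithmetic: expected
#' values add, entropies and hyper-entropies add in quadrature,
#' \deqn{Ex = \sum_i Ex_i,\; En = \sqrt{\sum_i En_i^2},\;
#'       He = \sqrt{\sum_i He_i^2}.}
#' This is the aggregation that turns per-index cloud weights into a
#' per-grade cloud connection degree.
#'
#' @param descs a non-empty list of [cloud_descriptor()] objects.
#' @return a single [cloud_descriptor()].
#' @examples
#' aggregate_clouds(list(cloud_descriptor(0.1, 0.03, 0.004),
#'                       cloud_descriptor(0.2, 0.04, 0.003)))
#' @export
aggregate_clouds <- function(descs) {
  if (!is.list(descs) || length(descs) == 0)
    abort_cmspa("'descs' must be a non-empty list of cloud descriptors",
                "cmspa_invalid_input")
  if (!all(vapply(descs, is_cloud_descriptor, logical(1))))
    abort_cmspa("all elements must be cloud descriptors", "cmspa_invalid_input")
  cloud_descriptor(
    ex = sum(vapply(descs, `[[`, numeric(1), "ex")),
    en = sqrt(sum(vapply(descs, `[[`, numeric(1), "en")^2)),
    he = sqrt(sum(vapply(descs, `[[`, numeric(1), "he")^2))
  )
}

#' Export cloud drops as delimited text
#'
#' Writes one CSV per cloud with columns `x` and `mu` and a header row; the
#' file name carries the concept label.
#'
#' @param drops a `cloud_drops` data.frame from [forward_cloud()].
#' @param label concept label used in the file name.
#' @param dir output directory (created if missing).
#' @return the path written, invisibly.
#' @export
write_droplets <- function(drops, label, dir = ".") {
  stopifnot(inherits(drops, "cloud_drops"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0("droplets_", gsub("[^A-Za-z0-9_.-]", "_", label),
                                ".csv"))
  utils::write.csv(as.data.frame(drops), path, row.names = FALSE)
  invisible(path)
}
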