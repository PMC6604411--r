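#' Validate a pairwise comparison matrix
#'
#' A pairwise comparison matrix holds Saaty-scale (1/9 .. 9) importance
#' ratios: unit diagonal and reciprocal symmetry a_ij * a_ji = 1.
#'
#' @param m square numeric matrix of positive entries.
#' @return `m`, invisibly, after validation.
#' @export
pairwise_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m) || nrow(m) < 2)
    abort_cmspa("'m' must be a square numeric matrix of dimension >= 2",
                "cmspa_invalid_matrix")
  if (any(!is.finite(m)) || any(m <= 0))
    abort_cmspa("pairwise comparisons must be positive and finite",
                "cmspa_invalid_matrix")
  if (any(abs(diag(m) - 1) > 1e-9))
    abort_cmspa("diagonal of a pairwise matrix must be 1", "cmspa_invalid_matrix")
  if (any(abs(m * t(m) - 1) > 1e-9))
    abort_cmspa("matrix is not reciprocal (a_ij * a_ji must equal 1)",
                "cmspa_invalid_matrix")
  invisible(m)
}

#' Priority weights from a pairwise comparison matrix
#'
#' Extracts the normalized principal right eigenvector by power iteration
#' (the canonical analytic hierarchy process prioritization); the row
#' geometric mean method is available as an alternative. For a perfectly
#' consistent matrix both recover the generating weight ratios exactly.
#'
#' @param m a reciprocal [pairwise_matrix()].
#' @param method `"eigen"` (power iteration, default) or `"geometric"`.
#' @param tol relative convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @return list of class `ahp_weights` with `weights` (named, positive,
#'   summing to 1) and `lambda_max` (the principal eigenvalue estimate).
#' @examples
#' eigen_weights(matrix(c(1, 3, 1/3, 1), 2, 2, byrow = TRUE))
#' @export
eigen_weights <- function(m, method = c("eigen", "geometric"),
                          tol = 1e-10, max_iter = 10000L) {
  method <- match.arg(method)
  pairwise_matrix(m)
  n <- nrow(m)
  ids <- rownames(m) %||% paste0("C", seq_len(n))
  if (method == "geometric") {
    w <- apply(m, 1, function(r) exp(mean(log(r))))
    w <- w / sum(w)
  } else {
    w <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      w_new <- as.numeric(m %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w) / pmax(w, .Machine$double.eps)) < tol) {
        w <- w_new
        break
      }
      w <- w_new
    }
  }
  lambda_max <- mean(as.numeric(m %*% w) / w)
  structure(list(weights = stats::setNames(w, ids), lambda_max = lambda_max,
                 method = method),
            class = "ahp_weights")
}

#' @export
print.ahp_weights <- function(x, digits = 4, ...) {
  cat(sprintf("<AHP weights> (lambda_max = %.*f, %s method)\n",
              digits, x$lambda_max, x$method))
  print(round(x$weights, digits))
  invisible(x)
}

# Saaty random consistency indices, n = 1..15
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59)

#' Consistency ratio of a pairwise comparison matrix
#'
#' CI = (lambda_max - n) / (n - 1), CR = CI / RI(n) with Saaty's random
#' indices. CR below 0.1 is conventionally acceptable. Matrices of dimension
#' 2 are always consistent (CR = 0).
#'
#' @param m a reciprocal [pairwise_matrix()] of dimension 2..15.
#' @return non-negative scalar.
#' @export
consistency_ratio <- function(m) {
  pairwise_matrix(m)
  n <- nrow(m)
  if (n > length(SAATY_RI))
    abort_cmspa(sprintf("no random index tabulated for dimension %d", n),
                "cmspa_unsupported_dimension")
  if (n <= 2) return(0)
  lambda_max <- eigen_weights(m)$lambda_max
  ci <- (lambda_max - n) / (n - 1)
  max(ci, 0) / SAATY_RI[n]
}

#' Two-level AHP hierarchy
#'
#' @param goal pairwise matrix comparing the middle factors against the goal.
#' @param criteria list with one pairwise matrix per middle factor, all over
#'   the same index set in the same order.
#' @return object of class `ahp_hierarchy`.
#' @export
ahp_hierarchy <- function(goal, criteria) {
  if (is.matrix(goal) && identical(dim(goal), c(1L, 1L))) {
    # degenerate single-middle-factor hierarchy: goal weight is 1
    if (!isTRUE(all.equal(goal[1, 1], 1)))
      abort_cmspa("a 1x1 goal matrix must be the identity comparison (1)",
                  "cmspa_invalid_hierarchy")
  } else {
    pairwise_matrix(goal)
  }
  if (!is.list(criteria) || length(criteria) != nrow(goal))
    abort_cmspa("'criteria' must hold one matrix per middle factor",
                "cmspa_invalid_hierarchy")
  dims <- vapply(criteria, nrow, integer(1))
  if (length(unique(dims)) != 1)
    abort_cmspa("criteria-level matrices must share dimension",
                "cmspa_invalid_hierarchy")
  ids <- lapply(criteria, rownames)
  if (!all(vapply(ids, function(x) identical(x, ids[[1]]), logical(1))))
    abort_cmspa("criteria-level matrices must share index ordering",
                "cmspa_invalid_hierarchy")
  for (cm in criteria) pairwise_matrix(cm)
  structure(list(goal = goal, criteria = criteria), class = "ahp_hierarchy")
}

#' Synthesize hierarchical AHP weights
#'
#' Final weight of index k = sum over middle factors f of
#' goal_weight_f * criteria_weight_fk: a convex combination of the
#' criteria-level weight vectors, so the result sums to 1.
#'
#' @param h an [ahp_hierarchy()].
#' @param method passed to [eigen_weights()].
#' @return named numeric weight vector summing to 1.
#' @export
synthesize <- function(h, method = "eigen") {
  if (!inherits(h, "ahp_hierarchy"))
    abort_cmspa("'h' must be an ahp_hierarchy", "cmspa_invalid_hierarchy")
  gw <- if (nrow(h$goal) == 1) 1 else eigen_weights(h$goal, method = method)$weights
  cw <- lapply(h$criteria, function(m) eigen_weights(m, method = method)$weights)
  out <- Reduce(`+`, Map(`*`, as.list(gw), cw))
  out / sum(out)
}
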