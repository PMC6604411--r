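#' Configuration for a synthetic expert panel
#'
#' Describes an expert panel to simulate: each expert scores each index on
#' the 10-point linguistic scale, drawn from a normal law centred at that
#' index's mean score with a common jitter, truncated to (0, 10]. Defaults
#' emulate the case-study panel: 10 experts, the fixture panel's per-index
#' mean scores, its pooled within-index standard deviation as jitter, and
#' integer scores (the linguistic scale is answered in whole points).
#'
#' @param n_experts number of experts.
#' @param means per-index mean scores in (0, 10]; named by index id (default:
#'   the case-study panel's row means).
#' @param jitter standard deviation of the truncated normal score noise,
#'   `>= 0` (default: the case-study panel's pooled within-index sd).
#' @param integer round scores to whole points (clamped to 1..10)?
#' @param seed optional default seed carried into [generate_panel()].
#' @return object of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_experts = 10, means = NULL, jitter = NULL,
                                   integer = TRUE, seed = NULL) {
  fix <- fixture_panel_scores()
  if (is.null(means)) means <- rowMeans(fix)
  if (is.null(jitter)) jitter <- sqrt(mean(apply(fix, 1, stats::var)))
  if (!is.numeric(n_experts) || n_experts < 1 || n_experts != round(n_experts))
    abort_cmspa("'n_experts' must be a positive integer", "cmspa_invalid_input")
  if (any(means <= 0) || any(means > 10))
    abort_cmspa("index means must lie in (0, 10]", "cmspa_invalid_input")
  if (jitter < 0)
    abort_cmspa("'jitter' must be non-negative", "cmspa_invalid_input")
  if (is.null(names(means))) names(means) <- paste0("K", seq_along(means))
  structure(list(n_experts = as.integer(n_experts), means = means,
                 jitter = jitter, integer = integer, seed = seed),
            class = "synthetic_panel_config")
}

# one truncated-normal draw per cell by rejection; jitter 0 short-circuits
rtrunc_scores <- function(n, mean, sd, lo = 0, hi = 10) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw > lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic expert judgment panel
#'
#' Draws scores independently per (index, expert) cell as configured;
#' deterministic given a seed. Integer panels round to whole points and
#' clamp to 1..10 so scores stay within the linguistic scale.
#'
#' @param cfg a [synthetic_panel_config()].
#' @param seed integer seed; overrides `cfg$seed` when given.
#' @return a [judgment_panel()].
#' @examples
#' cfg <- synthetic_panel_config(n_experts = 5, jitter = 0.5, seed = 42)
#' generate_panel(cfg)
#' @export
generate_panel <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "synthetic_panel_config"))
    abort_cmspa("'cfg' must be a synthetic_panel_config", "cmspa_invalid_input")
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  r <- length(cfg$means)
  scores <- matrix(0, nrow = r, ncol = cfg$n_experts,
                   dimnames = list(names(cfg$means),
                                   paste0("Expert", seq_len(cfg$n_experts))))
  for (k in seq_len(r))
    scores[k, ] <- rtrunc_scores(cfg$n_experts, cfg$means[[k]], cfg$jitter)
  if (cfg$integer) scores <- pmin(pmax(round(scores), 1), 10)
  judgment_panel(scores)
}
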