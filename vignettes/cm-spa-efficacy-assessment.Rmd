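---
title: "Cloud model-set pair analysis for efficacy grading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cloud model-set pair analysis for efficacy grading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmspa)
```

## The model

Set pair analysis (SPA) describes a system as a split of unit mass over an
identity component, several discrepancy components and a contrary component.
Applied to efficacy grading it becomes an m-element model: each clinical
index casts its full weight for exactly one of m ordered grades (here m = 5,
grade I best), and the total connection degree of a patient is the
weight-sum per grade,

$$\varphi_g = \sum_k \omega_k \, e_{kg},$$

with $e_{kg} \in \{0,1\}$ the one-hot evaluation matrix. When the weights
sum to one so do the $\varphi_g$: the connection degree is a distribution of
importance mass over grades, and the assessed grade is the one holding the
most mass (maximal connection degree principle).

The cloud-model arm replaces the scalar weights $\omega_k$ with *cloud
weights* $\omega(C)_k = (Ex_k, En_k, He_k)$ estimated from an expert panel.
After normalizing each expert's scores to unit mass, the backward cloud
generator is applied to each index's row of normalized judgments:

$$Ex_k = \frac{1}{N}\sum_l X_{kl}, \qquad
  En_k = \sqrt{\tfrac{\pi}{2}} \cdot \frac{1}{N}\sum_l |X_{kl} - Ex_k|, \qquad
  He_k = \sqrt{\left| s_k^2 - En_k^2 \right|},$$

where $s_k^2$ is the sample variance with denominator $N - 1$. $Ex$ is the
consensus weight, $En$ the between-expert fuzziness, $He$ the instability of
that fuzziness. Per-grade aggregation uses the independent-cloud arithmetic
($Ex$ adds; $En$, $He$ add in quadrature), yielding a *cloud connection
degree*: one normal cloud per grade instead of one scalar.

Interpretation uses the 3En rule — about 99.7% of a normal cloud's drops lie
in $[Ex - 3En,\, Ex + 3En]$ — to turn each grade's cloud into a decision
interval. The grade with maximal $Ex$ is primary; if no other supported
grade's interval intersects the primary's, the verdict is pure, otherwise
the grade with the largest overlap length is reported as secondary and the
verdict reads "between primary and secondary, closer to the primary". The
primary grade is always the closer one: the maximal-$Ex$ grade holds the
most mass by construction, and the blend only qualifies it.

## Numerical and design choices

**Backward-cloud estimators.** The entropy uses the plain (denominator $N$)
mean absolute deviation; the hyper-entropy subtracts $En^2$ from the
$(N-1)$-denominator sample variance and takes the absolute value before the
square root. The absolute value is not cosmetic: for small panels the
first-order $En$ estimate regularly exceeds $s$, and a dispersion parameter
must stay real and non-negative. This pairing of denominators is the one
that makes the estimator pair internally consistent on the bundled
case-study panel.

**Forward generator.** Each drop draws $En' \sim N(En, He^2)$, then
$x \sim N(Ex, En'^2)$ and $\mu = \exp(-(x - Ex)^2 / 2En'^2)$, with $\mu$
recomputed per drop using that drop's $En'$. Negative $En'$ draws are used
through their absolute value. The crisp descriptor $(Ex, 0, 0)$ yields all
drops at $Ex$ with $\mu = 1$ rather than an error, so pipelines degrade
gracefully when experts agree exactly.

**Fog.** A confusion degree $3He/En \ge 1$ means the drops no longer form a
bell — the concept is "fog". `cloud_weights()` emits a warning of class
`cmspa_fog` rather than failing: this is a data-quality signal telling the
analyst to re-elicit judgments, not a computational error. The crisp case
$En = 0$ has no confusion degree and raising it is an error of its own class.

**Grade boundaries.** Printed severity schemes routinely repeat boundary
values ("1-4" then "4-9") or leave integer gaps ("0-4" then "5-8"). The
classifier chains numeric ranges lower-exclusive/upper-inclusive with the
lowest interval closed at its lower endpoint, so wound area 1 cm² falls in
grade II while 0 cm² (the degenerate grade-I point) stays grade I, and
wound depth 0.5 falls in grade I. Integer-range indices close their gaps
downward: 4.5 wetted gauze layers grades with the "0-4" range. These
conventions are the unique set that makes classification total on each
index's domain while reproducing the bundled case study's 30 assignments;
the gap-closure rule is exercised by tests only, as no case-study datum
lands in a gap. Indices where large values are good (new-tissue area) list
their ranges per grade explicitly and are ordered internally, so no
monotonicity is assumed. Ties in the maximal connection degree are broken
toward the better grade and flagged with a `cmspa_tie` warning; real data
essentially never ties, but a deterministic, conservative rule is needed
for property tests.

**Zero grades and overlaps.** Grades supported by no index carry the crisp
zero cloud $(0, 0, 0)$ and are excluded from interval analysis. "Largest
intersection" is measured as overlap length of 3En intervals; touching
intervals (length 0) count as intersecting, which only matters in
pathological hand-built inputs. All intervals are computed from unrounded
values and rounded to 4 decimals for display only.

**AHP arm.** Priorities come from the principal right eigenvector of a
reciprocal pairwise matrix, computed by power iteration to relative
tolerance 1e-10; the row geometric-mean method is available as an option
since prioritization methods differ across the AHP literature and the two
coincide exactly on consistent matrices. Consistency uses
$CR = (\lambda_{max} - n)/(n-1)/RI(n)$ with Saaty's random indices for
$n \le 15$; $n \le 2$ is always consistent. In tests the power iteration is
cross-checked against a dense eigensolver, never replaced by it. The
case-study AHP weight vector is shipped as data because its source
comparison matrices are not recoverable from the publication; the engine is
validated on clean matrices instead.

## The synthetic panel generator

`generate_panel()` emulates an expert panel: per-index mean scores on the
(0, 10] linguistic scale, i.i.d. truncated-normal jitter per (index, expert)
cell, optional rounding to whole points (panels are typically collected as
integers). Defaults reproduce the bundled case-study conditions: 10 experts,
the case-study panel's per-index means, and its pooled within-index standard
deviation (about 1.4 score points) as jitter.

What it emulates — and what it does not: scores are independent across
experts and indices, so the generator captures marginal location and spread
but not inter-expert correlation (e.g. seniority-driven blocs) or
index-correlation structure present in real panels. Passing recovery tests
on synthetic panels therefore shows that the estimator chain is consistent
under the stated noise model, not that real panels satisfy that model.

## Problem sizes and determinism

The test suite checks droplet statistics at $10^3$–$10^5$ drops (stochastic
tolerances scale as $3En/\sqrt{n}$), grid-sweeps each numeric index at 401
domain points, and runs recovery on panels of up to 50 experts — sizes at
which every Monte-Carlo tolerance has comfortable margin while the whole
suite stays in the seconds range. All random draws take explicit seeds;
`forward_cloud()` and `generate_panel()` are bit-reproducible given a seed.

## Limitations

* Experts are equally weighted; roster metadata (position, experience) is
  carried but unused.
* One-dimensional clouds only; no multi-dimensional cloud concepts.
* The grading scheme is consumed as given — no clinical validation of the
  severity cut-points is attempted.
* The secondary-grade rule reports at most one secondary grade (the maximal
  overlap); profiles straddling three or more grades are summarized by the
  top pair, with all pairwise overlap lengths available in the verdict
  object.
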