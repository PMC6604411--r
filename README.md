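# cmspa

Cloud model–set pair analysis (CM-SPA) for grading the efficacy of
chronic-wound treatment, with an analytic hierarchy process (AHP) comparison
arm.

## The problem

Judging how well a diabetic ulcer responds to treatment means combining many
heterogeneous clinical indices — wound area (cm²), wound depth (cm), exudate
colour, necrotic-tissue fraction (%), pain (VAS), and so on — into a single
five-level efficacy grade, I (very high efficacy) through V. Two sources of
uncertainty make this hard:

1. **Index importance is elicited from experts** in linguistic terms, and
   experts disagree. Collapsing their judgments to a single constant weight
   per index discards that disagreement.
2. **The final grade is a qualitative concept**, and a patient whose profile
   straddles two grades should be reported as such, not forced into one bin.

CM-SPA addresses both with the *normal cloud model*: a qualitative concept is
represented by a triple *C = (Ex, En, He)* — expected value, entropy
(fuzziness/randomness of the concept), and hyper-entropy (the dispersion of
the entropy). The package is aimed at clinical-methods researchers working on
multi-criteria efficacy assessment with uncertain expert input.

## The method

For an expert panel scoring *r* indices (scores *x_kl* of index *k* by
expert *l*, on a 10-point linguistic scale):

1. **Normalization** — each expert's column is scaled to unit mass:
   *X_kl = x_kl / Σ_k x_kl*.
2. **Cloud weights** (backward cloud generator, per index row):

   * *Ex_k* = mean of *X_kl* over experts,
   * *En_k* = √(π/2) · mean |X_kl − Ex_k|,
   * *He_k* = √| s² − En_k² |, with *s²* the (n−1)-denominator sample
     variance.

   The cloud is sane when the confusion degree *3He/En* < 1; otherwise it is
   "fog" and the judgments should be re-elicited.
3. **Grading** — each patient index value is classified into grades I–V by a
   severity scheme (numeric ranges or categorical labels), giving a one-hot
   evaluation matrix.
4. **Cloud connection degree (CCD)** — for every grade, the cloud weights of
   the indices assigned to it are aggregated: Ex adds, En and He add in
   quadrature.
5. **Verdict** — the primary grade maximizes Ex (maximal connection degree
   principle); 3En intervals *[Ex − 3En, Ex + 3En]* of all supported grades
   are intersected. No intersection with the primary ⇒ a pure verdict;
   otherwise the grade with the largest overlap becomes the secondary grade
   ("between I and III, closer to I").

The AHP arm replaces cloud weights with a constant weight vector (principal
eigenvector of pairwise comparison matrices, Saaty consistency ratio) and
computes scalar connection degrees *φ_g = Σ_k ω_k e_kg*.

## Worked example

The complete case study — a 10-expert importance panel over indices K1–K10,
the 5-grade wound severity scheme, and three treated patients — ships with
the package:

```r
library(cmspa)
bundle <- load_fixture_bundle()

cloud_weights(bundle$panel)
#> <cloud weights>
#>  index      ex      en      he
#>     K1 0.11073 0.02169 0.00486
#>     K2 0.12116 0.01886 0.00515
#>     ...
#>    K10 0.08207 0.01385 0.00154

run_assessment(bundle$panel, bundle$scheme, bundle$patients)
#> <assessment result> mode = cm-spa, 3 patient(s)
#>   Cheng-ming Luan: The assessment completely belongs to grade I: its 3En
#>     interval does not intersect any other grade's.
#>   Di-he Gu: The assessment completely belongs to grade I: ...
#>   Hong-Liu: The assessment lies between grade I and grade III, closer to
#>     grade I (their 3En intervals overlap the most, length 0.0939).
```

Each cloud weight row reads: `ex` is the consensus relative importance of
the index (the `ex` column sums to 1), `en` the between-expert spread, `he`
the instability of that spread. The verdicts show the added value of the
cloud arm: under constant AHP weights Hong-Liu's grade-I and grade-III
connection degrees are nearly equal (0.3667 vs 0.3613) and the maximal-degree
rule silently picks I, while CM-SPA reports the blend explicitly.

A thin command-line front end covers the same surface:

```sh
Rscript inst/cli/cmspa.R assess --out-dir out            # case-study data
Rscript inst/cli/cmspa.R simulate --seed 7 --out-dir out # synthetic panel
Rscript inst/cli/cmspa.R droplets --ex 5 --en 1 --he 0.1 --n 1000 --seed 1
```

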