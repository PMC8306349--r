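---
title: "Meal-level food networks: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal-level food networks: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealnets)
```

This vignette explains the statistical machinery behind `mealnets`, the
decisions taken where the design was genuinely open, and what the
package's tests do and do not demonstrate about real recall data.

## Data model

The unit of observation is the *eating occasion*: a participant-labelled
meal within a 24-hour recall. Item-level records (participant, recall,
trimester, occasion label and order, food code, grams, kcal) are mapped
through a user-supplied taxonomy onto food groups and aggregated into a
`MealExperiment` (a `SummarizedExperiment`: food groups × meals, with the
meal keys in `colData`). Occasions labelled *supper* are analysed as
dinner. Labels outside the four network meal types follow a configurable
policy — defaults: *brunch* → lunch, *just a drink* → snack, *just a
supplement* → dropped. The defaults are explicit guesses where common
practice is silent; they preserve food intake while matching the four
meal types, and every mapping is logged. Multiple snack occasions in one
recall stay separate meals: meals are deliberately treated as independent
observations so that within-occasion food combinations remain visible,
at the cost of ignoring repeated measures per participant — which is why
the ICC table exists (below).

Two plausibility rules are applied before modelling. Recalls under 600
kcal are excluded as implausible; recalls over 4500 kcal are retained but
flagged for review (pregnancy raises energy requirements, so high totals
are treated as plausible). Food groups consumed in fewer than 5% of the
meals of a network are excluded from that network — strictly fewer:
exactly 5% is retained — to avoid over-representing associations between
episodically consumed foods that co-occurred a handful of times.

## Diet-quality scoring and stratification

The HEI-2015-style score has 9 adequacy and 4 moderation components,
each scored from an energy-adjusted density (per 1000 kcal or percent of
energy) linearly between a zero-point and a max-point standard and
clipped to [0, max points]; components sum to at most 100. Scoring
standards are **configuration, not code**: published standards are easy
to mistranscribe, so the package validates a user-supplied table
(13 components, 9 + 4, points summing to 100) and ships a clearly
labelled example file. The example encodes the fatty-acid component as a
plain density band because the package supports the two density units
only; users scoring real data should adapt that row to their own
documentation. Recalls are pooled per participant *before* densities are
computed (simple scoring, per person): pooling and per-recall averaging
genuinely differ whenever a component saturates, and the pooled order of
operations is the one implemented. Tertiles are assigned by ranking
totals; unequal remainders go to the low tertile first, ties break by
participant id — any convention works, this one is fixed and documented.

## Network estimation

Meal-level intakes are zero-inflated, skewed, and tied at zero, so the
Gaussian assumption is untenable on the observed scale. The package uses
the rank-based Gaussian copula route: Spearman correlations with
midranks (Kendall τ-b optional; both are exposed because field practice
cites both, Spearman-with-midranks is the default as the standard tie
treatment), mapped through `r = 2 sin(πρ/6)` (or `sin(πτ/2)`) to latent
correlations. The transformed matrix need not be PSD; eigenvalues are
clipped at 1e−6 and the matrix rescaled to unit diagonal (iterating, as
rescaling can nudge an eigenvalue back under the floor).

The graphical lasso solves
`max_Θ log det Θ − tr(RΘ) − λ Σ_{i≠j} |Θ_ij|`
by block coordinate descent over columns of the working covariance, a
soft-thresholded lasso per column; the penalty is applied to
off-diagonals only. Convergence is declared when the largest covariance
update in a sweep falls below `1e−5` times the mean absolute
off-diagonal of `R` (warning on hitting the 200-sweep cap). Zeros are
exact, so the edge set is read off the off-diagonals, with a `1e−8`
floor on partial correlations guarding float noise.

λ is selected by 5-fold cross-validation at the meal level (meals are
the analysis unit; participant-level folding is a sensible sensitivity
variant but meal-level is the default for the same reason meals are
independent observations). Held-out fit is the Gaussian log-likelihood
`log det Θ − tr(S_test Θ)` where `S_test` is the held-out fold's latent
correlation — evaluated on the same rank/sine scale the model was fitted
on, for internal consistency. Ties prefer the larger (sparser) λ. The
default grid is 15 log-spaced points on [0.01, 0.6], fixed once.

**A known property worth stating plainly:** with thousands of meals the
likelihood-optimal λ is small and retains many near-zero edges whose
held-out cost is tiny (order p²/n). Cross-validated likelihood argmax is
model-selection inconsistent for the graphical lasso: in the package's
own planted-truth experiments the CV-selected fit keeps every true edge
but adds tens of weak false ones, while moderately larger penalties on
the same grid recover the planted support exactly. The argmax rule is
the package default; `cvSelectLambda(..., rule = "1se")` selects the
sparsest model within one standard error of the optimum for users who
prioritize support recovery over predictive fit. Interpret weak edges
from large-n CV fits accordingly.

Trimester-specific networks re-apply the 5% filter on the trimester's
meals and refit at the pooled network's λ (no new CV); trimesters with
fewer than 20 meals are skipped with a warning.

## Communities and node roles

Louvain community detection runs on edge weights `|p_ij|` (resolution 1;
sweep order seeded, so results are reproducible and ties in ΔQ resolve
deterministically for a given seed). Reported communities have at least
two food groups; singletons are listed as conditionally independent
foods. The returned modularity is recomputed independently by the
package's own weighted Newman–Girvan formula as a self-check.

Node cartography uses binary edge counts by default — matching the
original within-module-degree/participation-coefficient method — with a
weighted variant exposed (`weighted = TRUE`); which of the two underlies
common practice is ambiguous, so both exist and the binary one is the
default. WC uses the population standard deviation within the community
(sd = 0 → WC = 0, so constant-degree communities are well-defined). The
role table classifies hubs (WC ≥ 1.0, a threshold adapted to sparse food
networks) by PC ≤ 0.30 / ≤ 0.75 / > 0.75 and non-hubs by PC ≤ 0.05 /
≤ 0.62 / < 0.80 / ≥ 0.80. The non-hub connector and non-hub kinless
bands overlap at exactly PC = 0.80: the package resolves PC = 0.80 as
kinless. PC values of real nodes rarely sit exactly on 0.80, but the
rule is total and documented.

Cross-stratum community numbering matches communities greedily by
decreasing Jaccard overlap of their node sets (threshold 0.25, ties by
community id, making the pairing symmetric in its arguments); unmatched
communities get fresh numbers.

## Variance decomposition

Per food group, on the observed gram scale including zeros (no
transformation is assumed; `log1p` is exposed for sensitivity):

* three-level: `y = μ + u_participant + v_mealtype + e`, crossed random
  intercepts via REML; `ICC_mealtype = σ²_v / (σ²_u + σ²_v + σ²_e)` is
  the share of intake variation explained by *which meal* it is. Meal
  type enters as a crossed random classification; with only four levels
  the meal-type variance is weakly identified, and the nested reading of
  the hierarchy is not materially different for the balanced structures
  involved.
* two-level, per meal type: `y = μ + u_participant + e`;
  `ICC = σ²_u/(σ²_u+σ²_e)` is between-participant share. A high value
  warns that the corresponding network node reflects a consumer subset
  (e.g. milk consumers vs non-consumers) rather than the stratum.

REML via `lme4` keeps variance components non-negative by construction;
ICC > 0.30 is flagged (strict inequality). For balanced designs the
one-way ANOVA method-of-moments estimator is kept as an independent test
oracle, and REML matches it to ~1e−7.

## The synthetic cohort

The generator exists so every downstream stage is testable end-to-end
with planted ground truth; its defaults are fixed as the package's
reference study conditions, not tuned per analysis:

* 120 participants per diet-quality stratum, one recall per trimester
  (second and third completed with probability 0.85), breakfast + lunch
  + dinner + 0–3 snacks per recall; dinner is labelled *supper* with
  probability 0.15, and occasional *just a drink* / *just a supplement*
  occasions exercise the label policy.
* 40 food groups; per-group consumption prevalence decays geometrically
  from 0.70 (roughly a third of groups fall under the 5% filter, like
  episodic foods in real recalls).
* One sparse precision matrix Θ\* per meal type × stratum (low/high;
  the mid stratum uses the elementwise average, SPD by convexity).
  Support is sampled with a per-node degree cap of 2 so the diagonal
  inflation needed for positive definiteness stays small and planted
  partial correlations keep magnitudes in [0.35, 0.5] (redraws bounded,
  deterministic given the seed).
* Zero inflation is a *single hurdle on one latent Gaussian*: group g is
  consumed when its latent coordinate exceeds τ_g = Φ⁻¹(1 − π_g), and
  the amount is exp(μ_g + σ_g Z_g) grams. Occurrence and amount are
  therefore governed by the same planted correlation — exactly the
  structure the copula model can partially see, which is what makes
  edge-recovery tests meaningful. This is a modelling decision of the
  generator, not a claim about real cohorts.
* Participant clustering enters the latent scale as an equicorrelated
  additive effect with variance share ρ_b = 0.15, mapping directly onto
  the two-level latent ICC.
* Energy densities (kcal/g) per group are hand-set constants; base
  portion sizes are calibrated once so recall totals centre near 2000
  kcal/day with small tails beyond both plausibility bounds, keeping the
  energy filter exercisable. The hurdle conditioning inflates consumed
  amounts ~1.5–3.5×, so base portions sit below typical served portions.
* Diet-quality totals are drawn per stratum (low ≈ N(45, 6²), mid ≈
  N(60, 6²), high ≈ N(75, 6²), clipped to [0, 100]) because computing a
  nutrient-level score for synthetic foods is out of scope; this
  suffices to exercise tertile assignment.

What the generator does **not** emulate: real food codes, seasonal or
day-of-week structure, recall-level reporting error, differential recall
completion by diet quality, or any missingness beyond varying recall
counts. Passing tests demonstrate the pipeline's correctness and its
behaviour under the copula-with-hurdle data model — not that the copula
model is right for any particular cohort.

## Numerical and testing choices

* Problem sizes in the test-suite recovery experiments — 100 random
  3×3/4×4 oracle comparisons, a p = 20 / n = 4000 planted-support run,
  a 3×3 variance grid at 200 participants × 8 meals, and a full pipeline
  at the default cohort size — were chosen as the smallest sizes at
  which the respective asymptotic behaviours are visible.
* Recovery simulations scale random draws to their exact target sample
  variance (moment matching). At 200 participants, the raw sampling
  error of a variance draw (~10%) can exceed the 0.05 ICC tolerance by
  itself; moment matching removes generator noise so the tolerance
  applies to the estimator under test.
* The test oracle for the graphical lasso is proximal-gradient ascent
  (ISTA with backtracking) on the exact penalized likelihood — a
  different algorithm family from the block coordinate descent it
  checks. A smoothed-gradient BFGS oracle was tried and discarded: its
  line search steps through the non-PD boundary.
* Degenerate inputs are contracts, not accidents: zero-variance retained
  columns error by name; empty meal matrices error; all-identical ICC
  inputs warn and return 0; chi-square tests with an empty margin return
  NA; unknown occasion labels error.

## Limitations

Meals as independent observations ignore within-participant correlation
in network estimation (quantified, not corrected, by the ICC table).
CV-argmax penalties over-include weak edges at large n (see above).
Louvain maximizes modularity greedily and can emphasize within-community
structure at the expense of strong between-community edges — node roles
(connector detection) partially compensate. The chi-square prevalence
comparison uses meal counts as denominators (matching "percentage of
meals"; a participant-level denominator is exposed by aggregating
upstream) and applies no multiplicity adjustment by default, with
Benjamini–Hochberg as an option.
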