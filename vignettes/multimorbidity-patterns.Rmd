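---
title: "Mining multimorbidity patterns with the standardised lift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multimorbidity patterns with the standardised lift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The analysis

`comorbnet` implements a pattern analysis of multimorbidity — the
co-existence of two or more chronic conditions in one person — for
survey cohorts recorded as a subject-by-condition binary table with a sex
stratum and a positive survey weight per subject. The pipeline has four
stages:

1. **Prevalence.** Survey-weighted prevalence per condition and stratum,
   the weighted morbidity-count distribution (multimorbidity prevalence,
   weighted median count), and per-condition chi-square tests of
   association with sex, corrected by the Benjamini–Hochberg false
   discovery rate.
2. **Association rules.** Every ordered condition pair A ⇒ B is scored by
   support P(A,B), confidence P(B|A), lift P(A,B)/(P(A)P(B)) and the
   *standardised lift*; rules above a standardised-lift threshold
   (default 0.2) are retained. Triads are scored analogously.
3. **Networks.** Retained rules define an undirected comorbidity network
   whose nodes carry weighted prevalence and whose edges carry the
   co-occurrence count; fast-greedy modularity maximisation partitions it
   into disease communities.
4. **Sensitivity.** The retained-rule count is recomputed across a grid
   of thresholds.

A latent-Gaussian cohort simulator with exact oracles backs all of this,
so every stage is validated against known ground truth rather than on
request-only survey data.

## The standardised lift

The lift of a rule A ⇒ B is the observed/expected ratio
P(A,B) / (P(A)P(B)); it equals 1 under independence. Its attainable range
depends on the margins: given P(A) and P(B), the joint probability is
confined to the Fréchet interval [max(P(A)+P(B)−1, 0), min(P(A),P(B))],
and an *observed* rule must additionally have support at least 1/n. A
fixed lift threshold therefore means different things for rare and common
conditions. The standardised lift removes that bias by rescaling the lift
onto [0,1] with its margin-specific bounds:

$$\mathrm{StdLift}(A \Rightarrow B) =
\frac{\mathrm{Lift} - \lambda}{\upsilon - \lambda},\qquad
\lambda = \frac{\max\{P(A)+P(B)-1,\; 1/n,\; s,\; c\,P(A)\}}{P(A)P(B)},$$

where *s* and *c* are the support and confidence floors imposed during
mining (both 0 by default: associations among rare conditions are kept).

**Upper-bound variant.** Two versions of the upper bound $\upsilon$
circulate: $1/(P(A)P(B))$, and the lift's true attainable maximum
$1/\max\{P(A),P(B)\}$ (reached when the rarer condition is a subset of
the commoner one). Only the latter reproduces the canonical worked value
for the female hypertension / high-cholesterol pair (margins 42.61% and
52.31%, joint prevalence 26.2%, n = 3347 give 0.6146 ≈ 0.61, versus 0.26
for the former), and only it maps [λ, υ] onto [0,1] tightly. The package
therefore defaults to `upper_bound_variant = "corrected"` and retains
`"as_printed"` behind a flag for auditability; a regression test pins the
asymmetry down.

**When is a rule defined?** A rule is scored only when both margins are
strictly inside (0,1), the observed support is positive (an association
rule must be observed at least once — precisely what the 1/n term in λ
encodes), and υ − λ ≥ 1e−12. Under those conditions the standardised lift
provably lies in [0,1]; the test suite verifies this exhaustively over
every 2×2 contingency table with n ≤ 40 (about 120,000 tables). Undefined
rules are carried as `NA` records rather than errors so full-matrix
outputs keep their shape.

**A property worth knowing.** Under the corrected bound, an independent
pair has standardised lift (1 − λ)/(υ − λ) ≈ max{P(A), P(B)}. Rules
involving a condition with prevalence above the threshold therefore clear
the cut even at independence; the measure ranks dependence *relative to
what the margins allow*, and for very common conditions even
independence sits mid-range. The parameter-recovery validation
(below) accounts for this.

**Weighting.** Margins, supports and confidences are computed from
survey-weighted proportions by default, matching the weighted prevalences
the rules are reported next to; the n in the 1/n term is always the
unweighted respondent count, since it encodes "observed at least once".
Whether the original analysis weighted these inputs is not documented;
`weighting = "unweighted"` gives the other convention, and with unit
weights the two coincide exactly (a tested invariant).

**Triads.** No published definition exists for a triplet's standardised
lift, so the package takes the maximum over the six single-versus-pair
bipartition rules ({X} ⇒ {Y,Z} and {Y,Z} ⇒ {X} for each choice of X),
with set-event probabilities as margins. This score is symmetric in the
triple and reduces to the pairwise spirit of the measure; it is an
interpretation, and it is labelled as such here. Triads are additionally
flagged when their weighted prevalence exceeds
`triad_min_prevalence` (default 5%).

## Statistical conventions

- **Chi-square tests** use unweighted 2×2 counts, 1 degree of freedom and
  no continuity correction (strata are large; the corrected statistic
  would not match the standard test the analysis names). Design-corrected
  survey tests are out of scope; both raw counts and weighted proportions
  are exposed so either convention can be audited.
- **FDR** is Benjamini–Hochberg, with q < 0.05 flagged. Under a simulated
  global null (20 conditions independent of sex, 500 replicates) the
  fraction of replicates with any discovery stays near the 5% level — a
  tested acceptance property.
- **Weighted median** morbidity count: the lowest count whose cumulative
  weighted proportion reaches 0.5 (deterministic, standard).
- **Zero-variance conditions** are reported as not-applicable rather than
  aborting the run.

## Community detection

Networks are built with one undirected edge per unordered pair retained
in either rule direction; edge weight is the unweighted number of
stratum participants with both conditions, node size attribute the
weighted prevalence. Community structure comes from agglomerative greedy
modularity maximisation (Clauset–Newman–Moore, as implemented in igraph):
the partition at peak modularity along the merge path is returned, so the
result is never worse than the trivial all-in-one partition (Q = 0).
Whether to use co-occurrence counts as modularity weights is not
documented in the motivating analysis; the package defaults to weighted
with `use_edge_weights = FALSE` available. The implementation is
deterministic for a given graph. On graphs small enough for exhaustive
search over all partitions (≤ 8 nodes) the greedy optimum is compared
against the true optimum in the test suite, and any gap is logged, never
hidden.

## The synthetic cohort generator

The generator is a Gaussian copula for correlated binary data: per
stratum it draws latent multivariate-normal vectors with a specified
correlation matrix and thresholds component k at the (1 − margin_k)
standard-normal quantile, so each condition's expected prevalence equals
its margin exactly. This supports arbitrary margins and calibrated
pairwise joint probabilities — the standard construction for correlated
binary simulation. Exact expected joints come from bivariate-normal
orthant integration (deterministic TVPACK quadrature), and
`calibrate_dependence()` inverts the orthant integral by monotone
bisection (tolerance 1e−8) so tests can plant a pair with a chosen lift.
Correlation matrices are accepted down to a smallest eigenvalue of −1e−8
(clipped to 0) to absorb floating-point asymmetry in user-entered
matrices; comonotone (singular) blocks are handled exactly.

Survey weights are log-normal with unit mean and dispersion (sdlog) 0.3 —
strictly positive and right-skewed like real survey weights — then
rescaled to an exact stratum mean of 1. The real survey's weight
distribution is not published; this model is a stand-in, not an estimate,
and the dispersion is configurable (`family = "constant"` gives
unweighted cohorts).

The study-scale default (`default_cohort_spec()`) emulates the motivating
survey's structure: 2,754 + 3,347 subjects, 31 conditions with the
published per-sex prevalences (0.15%–52.31%) as margins, and an
exchangeable latent correlation of 0.35 within five clinically grouped
blocks (cardiometabolic; musculoskeletal/frailty; respiratory; sensory;
other). The block structure keeps the matrix positive definite, produces
planted pairs comfortably above the 0.2 threshold, and gives community
detection a ground truth. What the generator does **not** emulate:
higher-than-pairwise dependence is inherited from the pairwise latent
structure rather than calibrated; age structure, non-response and the
survey's sampling design are absent. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted pairwise
structure, not fidelity to any real cohort.

## Validation design and problem sizes

The suite checks every stage against an independent oracle: orthant
probabilities against a Gauss–Legendre quadrature written separately from
the production path and against Monte Carlo; rule statistics and triad
scores against brute-force subset counting on enumerated fixtures (6 and
12 subjects); the standardised-lift bounds against exhaustive 2×2
enumeration to n = 40; communities against exhaustive partition search;
FDR behaviour against a 500-replicate simulated null (20 conditions,
1,000 subjects per stratum).

Parameter recovery uses 50 simulated cohorts of 5,000 subjects per
stratum with one pair planted at lift 1.5 (margins 0.45/0.48, latent
correlation calibrated through the copula oracle) among six mutually
independent background conditions with margins 0.03–0.12, prevalences
typical of the rarer conditions in the motivating survey. The planted
pair must be retained at threshold 0.2 in at least 95% of cohorts while
retained rules among the background pairs stay at a median of at most 2.
Background margins sit below the threshold deliberately: as noted above,
a pair involving a very common condition exceeds a 0.2 standardised lift
even at independence, so rules crossing from the planted (high-margin)
conditions to the background are a property of the measure, not false
positives of the implementation, and are excluded from the false-rule
count.

## Repository shape

The package is organised as an analysis workflow: the numbered drivers
under `analysis/` (simulate → prevalence → rules → networks →
sensitivity) narrate the study-scale run and write their tables under
`results/analysis/`, while every computation lives in the package
functions, which is what the tests exercise. `run_pipeline()` chains the
same stages programmatically and writes a manifest (seed, configuration,
versions, retained-rule counts) sufficient to reproduce every output
byte-for-byte.

## Known limitations

- The analysis is cross-sectional; longitudinal trends are out of scope.
- Rule mining is restricted to single-condition antecedents/consequents
  plus size-3 triads; no general frequent-itemset search and no
  alternative interest measures (conviction, leverage).
- Chi-square tests are not design-corrected for the survey weights.
- Community labels are structural only; assigning clinical names to
  communities is a manual act the package deliberately does not perform.
- The headline counts of any real cohort (retained rules, triad counts)
  depend on that cohort's dependence structure and are not reproducible
  from margins alone; the package validates against self-contained worked
  values and planted synthetic structure instead.
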