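---
title: "Fuzzy comprehensive evaluation of multifunctional rivers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy comprehensive evaluation of multifunctional rivers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverfce)
```

## The problem

A river serves environmental, ecological, social and economic functions at
once, and management decisions need a single defensible picture of how well
each function operates in each river segment.  `riverfce` implements a
hierarchical fuzzy comprehensive evaluation for this purpose.  The packaged
configuration arranges 22 indicators (C1--C22) under 12 sub-criteria
(B1--B12) and 4 criteria (A1 environmental, A2 ecological, A3 social, A4
economic), each indicator scored against five quality grades,
I (excellent) through V (poor), defined by per-indicator interval criteria.

The pipeline has three stages:

1. **Weighting.** Subjective weights from pairwise expert comparisons
   (analytic hierarchy process, AHP), objective weights from the dispersion
   of the observed data (entropy method), fused by a weighted average.
2. **Membership.** Each observed indicator value is converted into a
   five-grade membership vector by a Cauchy-shaped membership function
   parameterized from the grade intervals.
3. **Composition.** Memberships are composed with the weights into
   criterion- and target-layer evaluation vectors `D = W R`, and a grade is
   assigned by maximum affiliation.

## Grade intervals and the indicator system

Grade criteria are intervals with explicit endpoint closures, e.g. landscape
fragmentation (C11, smaller is better) has IV = (80, 90] and V = (90, 100].
Three special forms occur:

* **Unbounded extremes** such as dissolved oxygen (C6) grade I `> 7.5`.
* **Single-point grades**: a diversity index of exactly 0 (no species
  present) is its own worst grade, e.g. C7/C8/C9 grade V = {0}.
* **Bidirectional indicators**: water-resource utilization (C16) is best
  inside the band [25, 30] %, with two interval branches per lower grade on
  either side.
* **Categorical indicators**: surface water quality class (C4) takes the
  ordinal values 5..1 mapped to grades I..V.

The configuration ships as YAML and is validated at load time: exactly five
grades per indicator, pairwise-disjoint intervals, no coverage gaps between
adjacent grades, and a strict parent partition in the hierarchy.  Two
printed grade ladders end in an open bound immediately after a half-open
interval, which would leave the shared boundary value unclassifiable; the
packaged configuration closes the unbounded side there (C5 V as `>= 5`,
C19 V as `>= 80`, and C18 V as `[0, 5]`), preserving every printed boundary
value while keeping classification total.  C18's reversed interval notation
is stored in ascending order with the printed closures.  C15's printed unit
(million m^3/km^2) is stored as printed.

## AHP weights

Pairwise judgment matrices are positive and reciprocal with unit diagonal.
Priorities are the normalized principal eigenvector, computed by power
iteration (tolerance 1e-12 on the weight vector, cap 10,000 iterations);
positive matrices have a simple dominant eigenvalue, so the iteration is
exact in the limit and dependency-free.  The tests cross-check it against a
dense eigensolver.  Consistency uses
`lambda_max = sum_k (A w)_k / (n w_k)`, `CI = (lambda_max - n)/(n - 1)` and
`CR = CI/RI` with Saaty's random-index table (extended to n = 15); a matrix
is acceptable when CR < 0.1, and 2x2 matrices are consistent by
construction.  Global indicator weights multiply the criterion weight into
the within-criterion weights.  For the combined test across the hierarchy
the package reports the parent-weighted CI over the parent-weighted RI --
a convention choice, since several conventions circulate.

The original judgment matrices behind the packaged reference weights are
not available; `xiaoqing_judgment_matrices()` *reconstructs* exactly
consistent matrices from the published AHP weight column (`a_ij = w_i/w_j`)
and is documented as a reconstruction.  Log-normal noise and 1--9-scale
snapping can be layered on for simulation studies.

## Entropy weights

With `m` indicators over `n` segments, columns are min-max normalized
(direction-aware: positive `(x - min)/(max - min)`, negative
`(max - x)/(max - min)`).  Bidirectional columns are first folded to the
distance `|x - c|` from the center `c` of the ideal band (27.5 for C16) and
then treated as negative; categorical columns are treated as positive.
Proportions use the +1 shift `f_j = (1 + r_j)/sum(1 + r_j)`, and the
normalized entropy is `H' = -sum f ln f / ln n`, giving `H'` in [0, 1].
The weight is `w_i = (1 - H'_i)/(m - sum H')`.

Two degenerate-input rules matter:

* A **constant column** would divide by zero in the normalization; it is
  mapped to all 1s, so `H' = 1` and the weight is exactly 0 -- a constant
  indicator cannot discriminate between segments.  This is also internally
  consistent with the packaged reference table, where the
  ecological-flow-satisfaction indicator (excellent in every segment)
  carries entropy weight 0.0000.
* If **every** column is constant there is no information to weight and the
  computation aborts.

The entropy formula is implemented with the conventional minus sign; the
positive-signed variant sometimes seen in print would produce negative
entropies and is inconsistent with the zero weight above.

## Weight fusion

`fused = lambda * ahp + (1 - lambda) * entropy` with `lambda = 0.5` by
default: every row of the packaged reference table equals the arithmetic
mean of its AHP and entropy entries to the printed precision, which pins
the default.  Criterion-layer weights are **sums of member-indicator fused
weights**, not fusions of criterion-level columns -- only this rule
reproduces the reference table's criterion column (its A4 entry equals the
C18--C22 fused sum, not the mean of the printed criterion-level AHP and
entropy entries; the printed criterion-level entropy entry for A4 also
conflicts with its own column sum, so the package always reports the column
sum).  Criticality ranks are competition ranks computed at 4-decimal
precision, so printed ties share the smaller rank and skip the next.

## Cauchy memberships

For a grade with interval `[xl, xu]` of width `w`, the membership is
`r(x) = 1/(1 + a2 (x - a1)^2)`:

* **Interior grades II--IV**: `a1` is the interval midpoint and
  `a2 = 4/w^2`.  Consequently `r = 1` at the midpoint and exactly `0.5` at
  both interval boundaries, so two adjacent interior grades tie at 0.5 at
  their shared boundary.
* **Extreme grades I and V** peak at their *pole* -- the ideal endpoint for
  grade I, the worst endpoint for grade V, as oriented by the indicator
  direction -- and saturate at 1 beyond it.  A bounded extreme grade has
  membership exactly 1/5 at its inner boundary (since `a2 w^2 = 4`), safely
  below the adjacent interior grade's 0.5 there.
* **Unbounded extreme grades** borrow the adjacent grade's width `w_adj`:
  the peak sits at the shared boundary plus `w_adj` on the unbounded side,
  and the membership saturates beyond it.  The synthetic generator samples
  unbounded grades inside the same virtual bound.
* **Single-point extreme grades** (e.g. zero diversity) peak at the point
  with `a2` borrowed from the adjacent grade's width.
* **Bidirectional grades** evaluate each interval branch and take the
  maximum; the central band uses the interior parameterization, and the two
  outer branches of grade V are poles on their respective sides.
* **Categorical indicators** use a unit-width peak at each category value.

Composition uses the ordinary weighted-average matrix product
(`D_g = sum_i W_i R_ig`), the standard operator when the weight vector sums
to 1, which preserves every indicator's influence; the max-min operator is
available as an option for comparison.  Criterion-layer composition
renormalizes the fused weights within each criterion.  Ties in the maximum
affiliation resolve to the worse grade -- a deliberately conservative
assessment rule, stated in reports.  Evaluation vectors are reported raw
and normalized to sum 1; the assigned grade is unaffected.

Whether ordinal water-quality classes should be fuzzified at all is
debatable; the package fuzzifies them with the unit-width peak, which
makes an observed class dominate its own grade while letting adjacent
classes contribute 0.2 membership.

## The synthetic generator: what it emulates and what it does not

Real segment-level data behind published case studies are often not
deposited, so the generator produces scenarios with *planted* grade
structure: a segments x indicators grade table, values placed inside the
corresponding intervals (deterministic midpoints, or seeded uniform draws
avoiding boundaries by a relative margin of 1e-6), and judgment matrices
generated around known priority vectors with log-normal noise.  The
default scenario is a five-segment downstream-degradation ladder (segment
s planted at grade s) with the ecological-flow indicator excellent
everywhere -- emulating the qualitative structure reported for a real
lowland river (upstream best, downstream worst, flow requirement met in all
segments) and exercising the constant-column entropy path.

What passing tests on these scenarios show: the pipeline recovers known
structure -- planted grades, generating priority vectors, monotone
downstream degradation -- under controlled noise.  What they do not show:
anything about measurement error, spatial correlation between neighboring
segments, indicator interdependence, or time variation in real rivers; the
generator plants each cell independently and places values inside known
intervals by construction.

## Numerical choices and known limitations

* Power iteration tolerance 1e-12, cap 10,000; reciprocity checked to
  1e-9; weight vectors validated to sum to 1 within 1e-8 (1e-6 at the
  composition stage, where fused weights carry printed rounding).
* Criticality ties are detected at 4 decimals, matching published
  precision; full precision is kept everywhere else, with rounding only at
  display/export time.
* Seeded draws go through scoped RNG (`withr::with_seed`), so generating a
  scenario does not disturb the caller's RNG state, and every scenario
  records its seed.
* The problem sizes used in the shipped checks -- 5 segments x 22
  indicators, 100-200 random matrices of order 3-8, about 1,100 uniform
  recovery cells -- were chosen as representative of segment-level river
  assessments while keeping the full suite fast.
* **Single-point dominance zones.** Around a single-point worst grade
  (e.g. diversity index 0), continuity forces the point grade's membership
  to exceed the adjacent grade's within the lowest quarter of the adjacent
  interval: a diversity of 0.1 carries more affiliation to "no community"
  than to the (0, 1] class.  We consider this behavior defensible --
  near-zero diversity is ecologically closer to the absorbing state -- but
  it means fuzzy argmax and crisp classification deliberately disagree in
  those zones, and uniform-placement grade recovery is exact only outside
  them.  Midpoint-placed values recover their planted grades everywhere.
* The evaluation assigns the grade of maximum affiliation; when two grades
  carry nearly equal mass the single label hides a genuinely mixed state,
  so reports always carry the full membership vectors alongside the grade.
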