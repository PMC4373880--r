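---
title: "Methods: sums of squares, effect construction and paired power simulation in unbalanced 2x2 designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unbalanced 2x2 ANOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anova2x2)
```

## The model and its assumptions

Everything in this package concerns the two-factor linear model

$$Y = \beta_0 + \beta_1 A + \beta_2 B + \beta_3 AB + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2) \text{ i.i.d.},$$

where $A$ and $B$ are two-level factors and $AB$ is always the *product*
of the numeric codes assigned to $A$ and $B$. The model is assumed
homoscedastic and the noise normal; there are no covariates and no
within-subject structure. Two distinct questions are deliberately kept
apart:

1. **Construction** — which numbers the *world* substitutes for the factor
   levels when the data arise (`effect_spec()`); and
2. **Coding** — which numbers the *analyst* substitutes when fitting
   (`coding` argument of the engine functions).

Samples store abstract levels `C`/`T` precisely so that these two choices
cannot be conflated.

### Effect construction

`"zero_control"` substitutes (0, 1): control groups contribute nothing, so
with $\beta = (10, 4, 4, 4)$ the noise-free cell means are
$(10, 14, 14, 22)$. The interaction inflates both marginal differences
(from 4 to 6) and the grand mean, and only the remainder is left for the
interaction contrast — ANOVA's unique interaction SS understates the
generating $\beta_3$ by design of the world, not by a defect of the
estimator. `"equal_contribution"` substitutes (−1, 1): the same betas give
cell means $(6, 6, 6, 22)$, marginal differences of 8, and an interaction
contrast that carries the full $\beta_3$. With $\beta_3 = 0$ the two
constructions are affine relabellings of each other; with $\beta_3 \ne 0$
they are not (`cell_means()` makes this concrete), which is why rejection
rates for "the same betas" differ radically between constructions.

### Coding for analysis

Under (0, 1) treatment coding the interaction column is non-orthogonal to
both main-effect columns even in a balanced sample; under (−1, 1)
sum-to-zero coding it is orthogonal there. Consequences the test suite
verifies rather than assumes:

* $R(S)$ for the subsets $\{A\}, \{B\}, \{A,B\}, \{A,B,AB\}$ — hence all
  Type I and Type II quantities — are coding-invariant;
* the unique interaction SS $z$ is coding-invariant and identical across
  Types I, II and III;
* Type III *main-effect* SS are coding-dependent in unbalanced samples,
  and on balanced samples coincide with Types I/II only under contrast
  coding. The default coding everywhere is therefore `"contrast"`, with
  treatment coding available for the congruous/incongruous coefficient
  comparisons.
* the two codings' full-model coefficients are linked by the exact
  reparameterization $c_3 = b_3/4$, $c_1 = b_1/2 + b_3/4$,
  $c_2 = b_2/2 + b_3/4$, $c_0 = b_0 + (b_1+b_2)/2 + b_3/4$.

## The nested least-squares engine

All SS definitions are owned by this package rather than delegated to an
ANOVA routine: `nested_fits()` fits intercept-plus-$S$ for every non-empty
$S \subseteq \{A, B, AB\}$ and stores $R(S)$, the regression SS about the
grand mean. Because every predictor is constant within the four cells,
each fit collapses exactly to a weighted least-squares problem on the four
cell means with the cell counts as weights; the engine solves the centred
weighted normal equations (at most 3×3) with a relative singularity
tolerance of 1e-10 and raises a named error for an empty cell. This
collapse is what makes the Monte-Carlo study cheap: a thousand replicates
are a thousand rows of a cell-mean matrix pushed through the same small
matrix algebra. An independent brute-force oracle — explicit subject-level
design matrices and projection (hat) matrices — is kept in the test suite
and must agree with the engine to 1e-8 relative on randomly generated
samples, as must `stats::anova()` and `car::Anova()` types 2 and 3.

SS types are differences of the $R(S)$: sequential (Type I) in entry
order; Type II adjusts each main effect for the other main effect only;
Type III adjusts for everything. The Type II interaction row is defined as
the unique part $z = R(\{A,B,AB\}) - R(\{A,B\})$, the convention
statistical software uses even though Type II nominally assumes no
interaction. All F tests use the full-model residual mean square on
$N - 4$ df, the single residual line of a 2×2 ANOVA table.

The commonality decomposition (`venn_components()`) applies
inclusion–exclusion over the seven fits, yielding unique components $t, x,
z$ and cross-predictive components $u, v, w, y$ that may individually be
negative ("underlapping" variance); only their seven-way sum is additive.
$u + v = R(\{A\}) + R(\{B\}) - R(\{A,B\})$ is coding-invariant.

## The design space and the imbalance indicator

The study's designs are every composition of 12 base subjects over four
cells with at least 2 per cell — the minimum that leaves variance in every
cell — scaled by 10: 34 unbalanced patterns (numbered lexicographically by
$(n_{00}, n_{01}, n_{10}, n_{11})$) plus the balanced $(30, 30, 30, 30)$,
all with $N = 120$ and cells between 20 and 60. The per-effect imbalance
indicator is $U_V = (f_{V=T} - f_{V=C})/N$. For the interaction the
"treatment side" is not self-evident; this package assigns the concordant
diagonal cells $(0,0)$ and $(1,1)$ to the positive side, the sum-to-zero
view under which contrast coding compares the two diagonals. Swapping the
factor labels then swaps $U_A$ and $U_B$ and fixes $U_{AB}$, a symmetry the
tests exercise.

## The paired Monte-Carlo study

Study conditions (the package defaults): $\beta_0 = 10$,
$\beta_1 = \beta_2 = 4$, $\beta_3 \in \{0, 4, 8\}$, $\sigma = 10$, both
constructions, 1000 replicates per (design, $\beta_3$, construction) cell,
$\alpha = 0.05$, contrast-coded analysis. Per replicate the unbalanced
design and its balanced counterpart are filled from a shared per-cell pool
of $\max(d_j, b_j)$ subjects — the unbalanced arm takes the first $d_j$,
the balanced arm the first $b_j$ — so the arms share
$\min(d_j, b_j)$ subjects per cell. This common-random-numbers pairing
(the replicate-wise correlation of the arms' F statistics is positive, and
tested) sharpens the per-design comparison of rejection rates far beyond
what independent arms would allow at the same cost. The unbalanced arm is
analysed with SS II and SS III, the balanced arm with SS I.

**Seeding.** One base seed; every replicate's stream is derived by a
31-bit polynomial hash of (design id, $\beta_3$, construction, replicate
index), so any single replicate anywhere in the grid is reproducible in
isolation with `generate_paired(design, spec, seed = <derived seed>)`, and
identical grids plus base seed give byte-identical reports and output
files.

**Reporting.** `summarize_means()` averages rates over the 34 unbalanced
designs (the balanced column is the mean over the paired balanced arms).
`compare_to_balanced()` classifies each design against its *own* paired
balanced rate as higher/lower/tied — exact ties form a third category, so
the higher and lower percentages need not sum to 100 — with mean
differences $\Delta$ within the higher and the lower groups. The rule
"use SS II unless the interaction is significant" is reported as a rate
(`choose_ss2_rate`, the proportion of replicates in which the interaction
was not significant) rather than imposed as a gate, since both correction
methods are tabulated unconditionally. `coefficient_summary()` reports
the *mean over replicates* of the fitted coefficients and SS in a large
balanced design (default 250 per cell), which is the stabler of the
two natural readings (one huge dataset vs. mean of replicates) of such a
re-estimation table.

## The analytic oracle

For any design, spec, SS type and effect, `analytic_power()` computes the
noncentrality $\lambda$ as the noise-free effect SS — the engine run on
the expected cell means weighted by the cell counts — divided by
$\sigma^2$, and power as the noncentral $F(1, N-4, \lambda)$ upper tail at
the central-F critical value. Balanced examples at the study scale:
$\lambda = 4.8$ (marginal difference 4) gives power 0.585; $\lambda =
10.8$ gives 0.903; the unique interaction SS at $\beta_3 = 4$ under the
zero-control construction is $120$, so $\lambda = 1.2$ and power 0.192.
Every balanced simulation cell is required (in the acceptance tests) to
match this oracle within three Monte-Carlo standard errors; an effect with
zero noise-free SS must come out at $\alpha$ exactly.

A consequence worth stating: under the *equal-contribution* construction
with $\beta_1 = \beta_2 = 4$ the marginal differences are 8 and
main-effect power at $N = 120$ is $\approx 0.99$, near ceiling. Published
tabulations of this congruous condition sometimes show mid-range
main-effect power instead; no parameterization consistent with the stated
generator reproduces that, which is precisely why this package validates
its simulation against the closed-form oracle and the incongruous
(zero-control) condition's rates, and treats the congruous non-null rows
as analytically determined rather than as an external benchmark.

## Numerical choices and degenerate inputs

* Normal-equation solve with relative `rcond` tolerance 1e-10; rank loss
  and empty cells raise named errors.
* Cell counts below 2 are rejected at generation and at data import (no
  within-cell variance).
* An all-constant outcome yields $R(S) = 0$ for every subset; a sample
  whose effect SS is 0 with positive residual gives $F = 0$, $p = 1$.
* p-values are the upper-tail central-F probability; the tests
  cross-check them against an independent evaluation through the
  incomplete-beta representation to 1e-10.
* TSV report files print floating-point values to three decimals (the
  conventional precision for rejection rates); JSON mirrors full
  precision. Rates of exactly 0.0514 therefore print as `0.051` in TSV
  and 0.0514 in JSON.

## What the generator does and does not emulate

It emulates: two-level factorial treatment allocation with arbitrary cell
counts, i.i.d. normal noise with known $\sigma$, effects realised under
either construction, and attrition-free sampling. It does not emulate:
non-normal or heteroscedastic noise, covariates, within-subject designs,
informative dropout, or factors with more than two levels. Passing tests
therefore certify the algebra and the calibration of the F machinery
under the stated model — not robustness of SS II/III to violations of it.

## Known limitations

* With 1000 replicates the Monte-Carlo standard error of a rate near 0.05
  is about 0.007, and of a rate near 0.9 about 0.01. Statements of the
  form "rate within a ±0.014 band" or "strictly below the balanced rate
  in every one of 34 designs" are at the edge of that resolution: the
  analytic SS III deficit across designs ranges from about 0.004 to 0.018
  under the equal-contribution construction, so a handful of ties or
  sign flips among 34 paired comparisons is expected at this replicate
  count even though every deficit is negative in expectation. The
  acceptance tests state the strict forms and the package reports what it
  measures.
* The imbalance indicator is descriptive; it predicts the direction of
  SS II distortion only in the congruous condition.
* Type III under treatment coding is provided for completeness but is not
  a recommended analysis; its main-effect SS answer a question few users
  intend.
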