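---
title: "Selectivity scoring for kinase inhibitor screens: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selectivity scoring for kinase inhibitor screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsel)
```

## The problem and the data model

Kinome profiling screens report, for each compound at a single dose, the
percent by which it inhibits each kinase in a panel. `kinsel` works on this
matrix directly: rows are compound entries (the same chemical at two doses is
two independent rows, because selectivity is dose-dependent and single-dose
data cannot interpolate between doses), columns are kinases, and cells are
percent inhibition in [0, 100] or `NA` where the pair was never profiled.
Matrices from different screens are never merged: panels, assay conditions,
and doses differ, so each matrix is scored on its own.

Two source conventions exist. Percent-of-control files report residual
activity (0 = fully inhibited); these are converted on read as
`100 - value`, then clamped to [0, 100]. The clamp matters at both ends:
assay noise produces values slightly outside the physical range, and
compounds occasionally *activate* a kinase (percent of control above 100).
Activation is recorded as 0% inhibition rather than a negative number — a
negative cell would make the geometric mean undefined, and "activates the
kinase" and "does not inhibit the kinase" are equally disqualifying for an
inhibitor search.

## The selectivity score

For a chosen target set and one compound row, with measured target
inhibitions and measured off-target inhibitions $I_1,\dots,I_M$:

$$G = \Big(\prod_{t} I_t\Big)^{1/|T|}, \qquad
  P_b = \frac{1}{M}\sum_j I_j, \qquad
  P_n = \frac{1}{M}\sum_j \frac{I_j^2}{I_j + G}, \qquad
  S = G - P_b - P_n.$$

**The on-target score $G$** is the target's inhibition, or the geometric
mean over several targets. The geometric mean is deliberate: a compound
must inhibit *every* chosen target to be useful against the set, and a
single zero forces $G = 0$ where an arithmetic mean would reward partial
coverage.

**The broad penalty $P_b$** is the mean off-target inhibition. It is
panel-size-invariant: a compound that inhibits nearly everything at 10%
pays 10 points whether the panel has 50 or 500 kinases.

**The near penalty $P_n$** targets the opposite failure mode: a handful of
off-targets at a magnitude comparable to, or beyond, the target. Each
off-target contributes its inhibition weighted by $I_j/(I_j+G)$, a smooth
saturating weight that approaches 1 when $I_j \gg G$ and 0 when
$I_j \ll G$. There is no cutoff, binning, or tunable threshold anywhere in
the score — a design constraint, since any threshold would reintroduce the
arbitrariness the score exists to avoid. A term with $I_j = 0$ is defined
as 0 even when $G = 0$, which keeps the formula total.

**The composite $S = G - P_b - P_n$** uses unit weights and stays in
percent units, so scores are directly interpretable: $S \le G \le 100$,
with $S = 100$ attained exactly by a fully inhibiting, perfectly clean
compound, and $S \ge -200$ in the worst case. Additive combination is the
simplest form that preserves the properties the score is meant to have,
each of which is verified by randomized tests:

- $S$ strictly increases in any measured target inhibition and strictly
  decreases in any measured off-target inhibition;
- a compound that dominates another (every target cell at least as high,
  every off-target cell at least as low, same missingness) never scores
  lower;
- on the standard archetype panel the clean compound beats the pan-weak
  compound, which beats the few-strong compound (worked through below).

Missing cells are excluded from every sum rather than imputed: the score is
defined over the kinases *for which the compound has been profiled*, and
coverage counts (`n_targets_measured`, `n_offtargets_measured`) travel with
each score record so low-coverage scores can be discounted by the reader. A
compound with no measured target at all is flagged undefined and listed at
the bottom of the ranking, not silently dropped and not scored 0 — an
unprofiled compound is not evidence of a bad compound.

**Significant off-targets** are the kinases inhibited at least half as much
as the target ($I_j \ge G/2$, boundary included — "at least" reads as
inclusive). When $G = 0$ the ratio is undefined and every off-target with
any inhibition is reported.

**Ties** in the ranking break by descending $G$, then alphabetically by
compound label. This is pure plumbing, chosen so that repeated runs are
byte-identical; no scientific meaning attaches to it.

## Comparison metrics

Two single-number alternatives are provided for side-by-side columns, both
computed on a compound's full profile of measured values (targets included),
which is how they are used as whole-footprint summaries:

- the **Gini coefficient**, population form
  $\sum_{ij}|x_i-x_j| / (2n^2\bar x)$, with no $n/(n-1)$ sample correction
  (variants differ; the choice is stated in the output header). An all-zero
  profile returns 0 by convention. The implementation uses the sorted-order
  identity and is checked against a brute-force double loop to $10^{-12}$.
- the **S(x) score**, the fraction of profiled kinases inhibited at or
  beyond a threshold $x \in (0, 100]$ percent.

Neither references a chosen target, which is exactly their weakness: S(50)
cannot distinguish a perfectly clean compound from one that drags the whole
panel at 10%, and the Gini coefficient conflates "how concentrated" with
"concentrated on what". The test suite asserts this collapse concretely on
the archetype fixture. Entropy- and partition-based selectivity metrics are
deliberately absent: they require binding constants or IC50 values, which
the single-dose percent-inhibition data model does not carry.

## The synthetic-matrix generator

Real screen exports cannot be bundled, so the generator builds matrices from
the three archetypes any selectivity metric must separate, plus uniform
random filler rows:

| archetype | target cells | off-target cells | default |
|---|---|---|---|
| `clean_selective` | 90% | baseline | baseline 2% |
| `pan_weak` | 90% | all at `level` | level 10% |
| `few_strong` | 90% | `count` at `magnitude`, rest baseline | 5 at 90% |

The default panel is 51 kinases (one target plus 50 potential off-targets —
small for a kinome but large enough that five strong off-targets and a
pan-weak floor produce clearly separated penalties). Target inhibition 90%
and baseline 2% are fixture constants chosen once for reproducibility; any
values preserving the archetype contrast behave the same. On the noiseless
defaults the scores work out to

```{r archetypes}
sp <- synthetic_spec()
m <- generate_matrix(sp, "TARGET1")
rank_compounds(m, "TARGET1")[, 1:5]
```

and `archetype_expectations()` recomputes the same numbers in closed form
from the spec parameters, giving the ranking tests an oracle that never
touches a generated matrix.

Noise is additive Gaussian on the percent scale, truncated to [0, 100] —
the simplest model consistent with bounded percent data. Missing cells are
masked independently at a fixed rate. The generator seeds its own RNG and
restores the caller's stream, so identical specs yield byte-identical
matrices. What the generator does *not* emulate: kinase-family correlation
structure (related kinases are inhibited together in real panels),
compound-series similarity, dose structure, or heteroscedastic assay noise.
Tests passing on these fixtures show the scoring machinery is correct; they
do not show that the score's ordering is pharmacologically right on real
chemotypes, which only profiled reference compounds could.

## Parameters, defaults, and degenerate inputs

- **Target-set size**: 1–10 kinases. Ten is a query-interface convention,
  not mathematics, so `max_targets` can lift it (CLI:
  `--max-targets-override`).
- **Missing-value tokens** on read: `""`, `"NA"`, `"NaN"`, `"ND"`,
  configurable, because screen exports disagree on the dialect.
- **Kinase aliasing**: raw labels match case- and whitespace-insensitively;
  unknown labels pass through with a warning rather than erroring (no alias
  table covers every panel), and the package ships no default table — name
  standardization is screen-specific and user-supplied. Column collisions
  after renaming either error or merge by per-compound mean of measured
  cells (`on_collision`). Standardization is idempotent by construction.
- **Degenerate panels**: a matrix needs at least two kinase columns (a
  selectivity score needs a potential off-target); a row with no measured
  off-target gets $P_b = P_n = 0$ with a warning rather than an error, so a
  narrow panel still ranks.
- **Heatmap**: colour anchors black at 0, yellow at 50, red at 100. "Yellow
  = moderate" is anchored at the midpoint since nothing more specific is
  implied; the stops are configurable but must span [0, 100]. Missing cells
  are grey, visually distinct from black = measured-zero. The displayed
  page defaults to the top 10 ranked compounds, rows in exactly the current
  table order, and every image is written alongside an untransformed CSV of
  the same submatrix. Output formats are png and pdf.
- **Numerical tolerances**: the score formulas are closed-form arithmetic,
  so tests assert oracle agreement at $10^{-9}$ (score components) and
  $10^{-12}$ (Gini); the only floating-point subtlety is the sorted-order
  Gini identity, which is exact up to summation order.

## Problem sizes in the test suite

The randomized property tests run on 1,000+ random rows of 3–8 kinases
(oracle equivalence), hundreds of 10–20-kinase rows (monotonicity,
dominance), 51–100-kinase synthetic panels (ranking, coverage,
determinism), and 10 seeds × 1,000 cells for the binomial coverage check —
sizes at which the closed-form oracles are trivially trustworthy and the
full suite runs in well under a minute of compute.

## Limitations

Everything here is computed from single-dose in vitro inhibition data.
Selectivity at 1 µM in a biochemical assay may not survive contact with a
cell: compound uptake, metabolism, target abundance, and pathway context
all intervene, so the ranking is a data-driven shortlist generator, not a
substitute for validation. Scores are comparable only within one matrix —
never across screens run under different conditions — and the raw score is
reported without rescaling, so its absolute value inherits the dose and
panel of the source screen.
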