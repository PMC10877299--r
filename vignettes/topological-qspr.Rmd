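---
title: "Degree-based topological indices and univariate QSPR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and univariate QSPR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoqspr)
```

This vignette is the package's account of its model, its numerical
choices, and the design decisions that were genuinely open. It states
no empirical result that the test suite and `scripts/acceptance.R` do
not themselves compute.

## The molecular-graph model

A molecule is reduced to its **hydrogen-suppressed graph**: vertices are
heavy atoms, and every bond — single, double, triple or aromatic —
contributes exactly one edge. The result is a finite, connected, simple
graph. This collapse is deliberate and load-bearing: every index
computed here is a function of the degree sequence over edges only, so
bond orders, charges, stereochemistry and element identities are
irrelevant to the outputs (element symbols are retained as vertex
metadata, nothing more). For acetaminophen the hydrogen-suppressed
skeleton has 11 atoms and 11 edges, and only that graph — not the
20-atom all-atom graph — reproduces the published index row, which is
the empirical anchor for both conventions.

Two input routes exist and are tested to agree: SMILES (parsed through
OpenBabel via ChemmineR) and a plain edge-list text format defined by
this package (`"u v"` pairs, optional `name` header, `#` comments). The
edge-list reader treats duplicate edge lines and self-loops as errors
rather than repairing them, because its fixtures are hand-transcribed
and silent deduplication would hide transcription mistakes.

## The edge partition and the index engine

Grouping edges by the unordered endpoint-degree pair `(lo, hi)` gives
the **degree-pair edge partition**, the sole input to all fourteen
indices: each index is `sum(count * f(lo, hi))` over occupied classes.
All indices share one summation engine keyed by `f`; adding an index is
a one-line registration. Drug-like graphs have maximum degree 4
(carbon valence), so at most the eight classes between `(1,2)` and
`(3,4)` occur; `validate_chemistry()` warns — does not fail — on
higher degrees, since hypervalent S and P are chemically possible.

Degenerate inputs are kept total: an edgeless graph (single heavy atom)
has an empty partition and every index is defined as 0 there, rather
than erroring, so batch computations never fall over on methane-like
entries.

### The harmonic-index convention

The defining formula of the harmonic index is `H = Σ 2/(d_x + d_y)`.
The published anti-hepatitis tables, however, tabulate the *halved*
variant `Σ 1/(d_x + d_y)`: for acetaminophen the formula gives 4.90
while the printed value is 2.45, and the factor is exactly 2 for every
graph. Rather than guessing which the authors intended, both are
implemented: `harmonic = "standard"` (the formula; the default) and
`harmonic = "paper_table"` (the printed convention, used by all
table-reproduction code and the golden regression fixtures). A
property-style test asserts the exact 2× relation on random partitions.

### Rounding

Internal computation always keeps full precision. For reporting,
`format_index_table()` rounds the irrational-valued indices to 2
decimals with R's round-half-even. The published tables *truncate*
rather than round at 2 decimals (e.g. GA = 10.4766 prints as 10.47), so
wherever recomputed values are compared against printed ones, agreement
"to 2 dp" is asserted as an absolute difference below 0.01, never
tighter.

## The study dataset

The 16 drug structures exist in the source only as drawings, so the
SMILES fixtures are curated from standard published structures, each
with a provenance note (`drug_provenance.csv`). Curation was verified
where possible: acetaminophen reproduces its full printed index row (a
hard integrity check in `hep_drugs()`), and most of the well-known
structures reproduce the printed Z1/Z2 exactly. Five large NS3/NS5A
inhibitors are approximate reconstructions — flagged `synthetic` in
their provenance — whose macrocyclic detail could not be verified
against a drawing; per design, their recomputed rows flow into an audit
table (`audit_recomputed()`), never into hard assertions.

The printed index tables are stored **verbatim**, kept strictly apart
from recomputed values, because several printed rows are internally
impossible: the identity `HZ = F + 2·Z2` holds exactly for every graph,
and six printed rows violate it. `audit_identity()` flags these and
never rewrites them. The regression-reproduction code therefore fits on
the *printed* index values by default (`index_source = "paper_printed"`),
isolating regression verification from structure-transcription
differences.

The property table preserves the published `value±uncertainty` cells
and missing entries. Uncertainties are parsed and stored but unused by
the regressions (the source fits are unweighted; the varying sample
sizes 9–16 match plain listwise deletion, which weighted fitting would
not change anyway). Units are opaque labels — the source never states
them. Vapor pressure is printed as 0.0 for every drug; a zero-variance
response makes the regression undefined, so VP fits are reported as
`available = FALSE` rather than fabricated.

## The regression model

For each of the 11 properties and 14 indices: listwise deletion of
absent cells, then ordinary least squares of `P = x + y·TI`, Pearson
`r`, `r² = r^2` exactly, and the two-sided p-value of the slope
(`t = r·sqrt((n−2)/(1−r²))` on `n−2` df, identical to the `lm`
summary). Significance is declared at `p ≤ 0.05`. Pairs with fewer
than 3 complete observations or degenerate variance are carried as
unavailable rows so a batch run always completes. No multiple-testing
correction is applied — deliberately matching the source methodology —
and this is a real caveat: 154 fits at α = 0.05 will produce false
positives among the weak correlations.

Best-descriptor ranking maximizes |r| per property; ties break by index
declaration order (the `index_names()` order), which is documented
rather than left to sort instability. Scatter plots are drawn only for
fits with r² ≥ 0.8, matching the source's plotting rule; plots are
optional artifacts, never part of any assertion.

## The synthetic-data generator

`generate_graph()` emulates the study conditions: connected simple
graphs with maximum degree 4. Construction is a random tree grown
vertex by vertex (each new vertex attaches to a uniformly chosen
existing vertex with spare degree budget) followed by `n` ring-closure
attempts accepted with probability `ring_probability` when feasible.
Connectivity is guaranteed by construction; the tree-plus-rings shape
mimics acyclic-plus-ring drug skeletons. Defaults are chosen once to
match the study drugs: `max_degree = 4`; sizes drawn from 11–65
vertices (the heavy-atom range of the 16 drugs); `ring_probability =
0.2`, giving on the order of one ring per 7–10 vertices, comparable to
the fixtures. Randomness is base R's Mersenne-Twister, seeded
explicitly through every entry point with `withr::with_seed`, so equal
seeds give byte-identical output.

`generate_property_table()` inverts the regression model:
`value = intercept + slope·TI + N(0, noise_sd²)`, with cells removed at
a configurable rate to exercise listwise deletion, and the generating
parameters attached as ground truth. The calibration experiments use a
study-scale model — `P = 50 + 2.5·Z1 + N(0, 25²)`, shaped like the
molar-weight regression — with 500 replicates over 200 graphs for
parameter recovery (estimates within 4 standard errors of truth) and
2000 replicates at the study's sample size of 16 under a zero slope for
the size of the t-test (rejection rate 0.05 ± 0.02). These problem
sizes are the package's chosen compromise between Monte-Carlo precision
and a test suite that stays fast.

What the generator does **not** emulate: chemical validity (no element
or valence assignment beyond the degree cap), realistic property
distributions (only linear-plus-Gaussian), or correlated missingness
(the study's missing cells are concentrated in specific drugs;
generated missingness is independent). Passing calibration therefore
demonstrates the statistical machinery is correct, not that real
properties are linear in any index.

## Numerical and design notes

- Integer-valued indices (Z1, Z2, Z3, ReZG3, RZ2, HZ, F) are exact in
  double arithmetic for any realistic molecule; identity tests assert
  them with zero tolerance. Rational ones (IS, SDD) accumulate benign
  float error (e.g. `(1/3 + 3)·3` ≠ 10 exactly), so they are compared
  with tolerances.
- Edge partitions are computed once per graph at construction and
  cached inside the `mol_graph`, since graphs are immutable after
  validation; this makes replicate-heavy simulations cheap.
- The command-line surface is a thin `Rscript` wrapper
  (`inst/cli/topoqspr.R`) over exported functions; exit codes are 0 /
  1 (validation) / 2 (I/O).
- Known limitations: univariate models only (no multilinear QSPR,
  cross-validation or applicability-domain analysis); five structure
  fixtures are approximate reconstructions; the published tables
  contain misprints that are audited, not resolved; and with n = 9 for
  four of the properties, the reported correlations carry wide
  confidence intervals.
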