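---
title: "Street-audit scoring and reliability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Street-audit scoring and reliability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastview)
library(dplyr)
```

`fastview` implements a complete street-audit workflow around the FASTVIEW
walkability instrument: instrument definition and record validation,
ordinal data reduction, audit-link sampling from a road network, and the
three reliability analyses (intra-rater, inter-rater, criterion) with a
simulator that gives every statistic a recoverable ground truth. This
vignette explains the methods, the tunable parameters, and the choices made
where the design was genuinely open.

## The instrument and its polarity model

The instrument groups 26 observable street factors into nine walkability
categories (pavement width and obstructions, pavement surface quality, kerb
paving quality, road permeability, way finding and legibility, lighting,
personal security, user conflict, environment quality). Each factor offers a
fixed ordered list of response levels, printed from the most positive option
through to the most negative; some factors additionally allow N/A. The
bundled JSON definition materializes a polarity tag per level under the
positional rule this ordering implies:

* first listed non-N/A level → `positive`
* last listed non-N/A level → `negative`
* everything between → `intermediate`
* the N/A level (where allowed) → `not_applicable`

Two consequences are worth knowing. Two-level factors ("Landmarks; no
landmarks") have one positive and one negative level and no intermediate.
And the rule is strictly positional: for "Obstruction from bus queues" the
first-listed level "Yes" is tagged positive because that is the printed
order, even though one might read the wording the other way. Users who
disagree with a printed ordering can edit a copy of the schema JSON — the
loader re-validates the polarity pattern, so only whole-level reorderings
are accepted, not arbitrary tags.

Level codes are stored verbatim (en-dash ranges like "2–3" included) and
matched case-insensitively with an ASCII-hyphen alias, so hand-typed CSVs
with "2-3" or "Poorly placed" validate cleanly.

## The good/fair/poor reduction rule

Each audit unit is rated per category on a three-point ordinal scale:
*good* (2) when every non-N/A response in the category is its factor's
positive extreme, *poor* (0) when every one is the negative extreme, *fair*
(1) otherwise, and missing when every response is N/A. "Otherwise" is doing
real work: an intermediate response anywhere forces fair, even if all other
responses are negative — consistency means consistency at the extreme. A
majority rule would be an alternative reading; the all-extremes reading is
the one compatible with the instrument's worked example (wide pavement +
aligned furniture + no pavement parking → 2), and it is what
`score_category()` implements. The rule depends only on polarity tags, never
on level wording, and is monotone: nudging any single response one step
toward the positive end never lowers the category rating (this is enforced
by an exhaustive enumeration in the test suite).

Both road sides of a link are audited where possible. The statistics need
one rating per link, and the combination rule is not dictated by the
instrument; `combine_link_sides()` defaults to the **minimum (worst side)**,
on the view that a link's walkability is constrained by its least walkable
usable side, with `rule = "max"` available. A link audited on one side only
(e.g. pavement on one side) carries that side's rating through.

## Rating matrices and the three designs

`build_rating_matrix()` shapes scored audits for one category into the
items × columns table the agreement statistics consume:

| design | items | columns |
|---|---|---|
| `inter_rater` | links | raters (one occasion, one mode) |
| `intra_rater` | (rater, link) pairs, pooled | occasions 1 and 2 |
| `criterion` | (rater, link) pairs | modes: desk imagery vs on-site |

Pooling (rater, link) pairs for the intra-rater and criterion designs
reports a single column per design rather than per-rater results (per-rater
reporting is available by filtering the scored table first). The criterion
design pairs each rater's own desk and on-site audits; mixing raters across
modes would confound mode disagreement with rater disagreement. Cells with
more than one candidate audit are an error (duplicate data); items with any
missing cell are dropped listwise within a category, with the count logged.

## Agreement statistics

**Percent agreement** is the share of complete items on which the compared
columns give identical ratings. For more than two columns the default is
the mean of all pairwise two-column agreements; an all-columns-agree variant
(`method = "all"`) is stricter and provided as an option.

**Cohen's kappa** (`cohen_kappa()`, two columns) corrects observed
agreement for chance using the product of the two columns' marginal
distributions: κ = (p_o − p_e)/(1 − p_e). **Fleiss' kappa**
(`fleiss_kappa()`, m ≥ 2 columns with equal raters per item) uses per-item
pair agreement and pooled category proportions. Both are computed on the
unweighted three-level scale — a weighted kappa would need a distance
between good/fair/poor that the instrument does not define. With two
columns Fleiss' statistic is its two-rater special case (pooled marginals)
and is intentionally not forced to equal Cohen's.

Kappa is undefined when expected agreement is 1 (zero-variance marginals,
e.g. both columns constant and identical). The package returns `NA` with a
warning rather than substituting 0 or 1, and reports always carry percent
agreement alongside kappa: the statistic is prevalence-sensitive and can be
near zero, or negative, despite 90% raw agreement — the bundled published
scores contain exactly such a case (user conflict, intra-rater: 90%
agreement, κ = −0.05).

Bands via `interpret_kappa()` follow the conventional Landis–Koch labels
(0.01–0.20 slight, 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80
substantial, 0.81–0.99 almost perfect), with ≤ 0 labelled "poor/less than
chance", exactly 1 "perfect" and `NA` "undefined".

Report tables round half away from zero — percentages to one decimal, kappa
to two — so printed output is platform-stable. Underlying tibbles keep full
precision; summaries (mean/min/max across the nine categories) skip
undefined kappas with a logged note.

```{r published}
fastview_published_scores() |>
  filter(design == "criterion") |>
  summarize_reliability()
```

## Sampling geometry

The audit area is a disc (default radius 800 m, roughly a ten-minute walk)
around a study centre point — computing a population-weighted centroid is a
GIS/census step outside this package; supply the point. Coordinates must be
planar metres: all thresholds are metric, so project longitude/latitude
first.

`clip_network()` intersects each junction-to-junction edge with the disc by
solving the segment–circle quadratic per polyline segment; edges are split
at the boundary and partial edges are retained (the disc defines the audit
area, not edge membership — a config-free choice, since excluded stubs fall
out at the minimum-length rule anyway). `segment_links()` then applies the
link rules: edges shorter than `min_length` (default 50 m) are excluded
rather than merged across junctions (links are defined junction-to-junction);
edges up to `max_length` (default 300 m) become one link; longer edges are
split into ⌈L/300⌉ **equal-length** parts, which keeps links homogeneous
and can never create a sub-50 m remainder, unlike splitting into 300 m
pieces plus a tail. `sample_links()` draws a seeded simple random sample of
`round_half_up(fraction × n)` links — the half-up rule makes a 25% draw
from 216 eligible links exactly 54.

## The simulation model

The simulator operates at category-rating level, where every reliability
statistic lives: each link gets a true rating per category drawn from a
prevalence vector, and each audit reports the truth filtered through a 3×3
row-stochastic confusion matrix, independently across links, categories,
raters, occasions and modes. Independence buys a closed form:
`theoretical_kappa()` enumerates the 27-point (truth, report A, report B)
space to give the exact two-rater kappa the empirical statistics should
recover, which the tests verify at n = 500 links (within ±0.05 for at least
19 of 20 seed/parameter draws).

Defaults define the reference study conditions and mirror the original
evaluation's shapes: 3 raters; 54 links rated once by all raters
(inter-rater); 20 links rated on two occasions by each rater, pooled to a
60 × 2 matrix (intra-rater); 30 links assigned round-robin to raters and
audited in both modes (criterion). Prevalence defaults to (0.2, 0.5, 0.3)
over poor/fair/good — on UK residential streets most categories are neither
uniformly excellent nor uniformly absent, so fair dominates. Rater accuracy
defaults to 0.9 (symmetric errors) for desk audits and 0.95 on-site,
reflecting that imagery obstructions (parked cars, weather, camera
viewpoint) degrade desk audits but not on-site ones; no occasion drift is
modelled. A secondary factor-level path (`simulate_audit_records()`) draws
level codes consistent with the truth and flips factors with a configurable
probability, exercising validation and scoring on wide records.

What the simulator deliberately does not emulate: land-use heterogeneity
(the documented driver of low inter-rater agreement in industrial areas),
correlated errors between categories or occasions, temporal change between
imagery capture and on-site visits, and anything about imagery itself.
Passing tests therefore demonstrate that the statistics and pipeline are
correct, not that any particular field deployment will reach a given
agreement level.

## Published scores and what is checkable

The per-category percent agreement and kappa values from the instrument's
original field evaluation are bundled (`fastview_published_scores()`); the
underlying link-level audit records were never published, so per-category
values cannot be recomputed from data. The package's checks therefore rest
on three legs: summaries over the published per-category values (means and
ranges per design), the printed design counts (54 = 25% of 216; 60 × 2;
30 × 2), and property-based suites against independent oracles (brute-force
contingency kappa over all 729 two-rater three-item matrices, a direct
transcription of the Fleiss formula, pairwise-agreement enumeration, and
Monte-Carlo recovery of the closed-form kappa). Test problem sizes — 500
links for recovery runs, 1000 random synthetic edges for segmentation, 2000
seeds for sampling frequencies — were chosen to make binomial noise small
relative to the tolerances while keeping the default suite quick.

## Numerical notes and limitations

* Geometric tolerances: 1e-6 m for length conservation and the 300 m upper
  bound; circle crossings are dropped within 1e-12 of a segment endpoint to
  avoid zero-length pieces.
* Kappa comparisons against oracles hold to 1e-12; the undefined-kappa
  guard triggers when 1 − p_e falls below the square root of machine
  epsilon.
* No confidence intervals or significance tests for kappa are provided, and
  no cross-category walkability index is computed — the instrument reports
  per-category results only.
* Stratified reliability (e.g. by land use) is possible by filtering the
  scored table before reporting, but no stratified reference values ship
  with the package.
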