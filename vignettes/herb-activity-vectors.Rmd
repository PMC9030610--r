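---
title: "Activity vectors, exact k-means, and herb characters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity vectors, exact k-means, and herb characters: methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbvec)
```

## The measurement scale

Every activity value handled by this package is **percent of control
remaining**: 0 means the endpoint was fully suppressed, 100 means no effect,
and values above 100 mean enhancement. The packaged example panel contains a
genuine case of the latter (A. dahurica, enzymatic lipid peroxidation, 149 —
a pro-oxidant response), which is why values are validated as non-negative
but *not* capped at 100. Two converters cover the usual raw forms:
`inhibition_to_remaining()` (percent inhibition to percent of control,
`100 - x`) and `raw_to_percent_of_control()` (`100 * treated / control`,
requiring a positive control).

This scale is inverted relative to intuition — **low numbers mean high
activity** — and that inversion propagates through everything downstream:
small magnitude scores identify the most active herbs, and the canonical
cluster 1 is the one with the smallest centroid norm. Reports and plot
subtitles restate "0 = maximal inhibition" because this is the easiest
convention to misread.

## Magnitude scores

A score is the Euclidean norm of a herb's values over a named endpoint
subset (`vector_space()`). The defaults are:

* `alpha` — (LNE, LE): the two lipid-peroxidation assays;
* `beta` — (L5, COX1): 5-LOX and COX-1 inhibition;
* `chi` — (L5, COX1, L12): the full eicosanoid panel.

Scores are rounded to the nearest integer, ties away from zero; both the
unrounded (`rounding = "none"`) and rounded forms are available.

**Why `alpha` defaults to two endpoints.** The example panel's published
magnitude column is reproduced exactly by the (LNE, LE) norm for 11 of the
15 herbs, whereas the three-endpoint norm (LNE, LE, XO) reproduces it only
for A. dahurica (191 = sqrt(94² + 149² + 74²), while sqrt(94² + 149²)
rounds to 176). Three further herbs (A. sinensis, C. pilosula, C. chinensis)
differ from the printed value by exactly one unit under *any* integer
rounding of the two-endpoint norm — the signature of magnitudes originally
computed on unrounded component values that were later printed as integers.
The package therefore defaults to the definition with the largest exact
agreement, documents the four exceptions in its tests, and exposes
`alpha_endpoints = c("LNE", "LE", "XO")` as a switch; when the switch is
used, herbs lacking an XO value lose their alpha under the default missing
policy. The `beta` and `chi` columns are reproduced exactly for all 15 and
all 11 printed values respectively.

**Missing policy.** `drop_herb` (default) gives a herb `NA` for a score if
*any* endpoint of that space is missing — matching the convention that the
(α, χ) analysis uses only the 11 herbs with a 12-LOX measurement.
`available_case` instead takes the norm over whatever endpoints are present;
it is appropriate for exploratory use but changes the meaning of the score
(norms over fewer components are systematically smaller), so it is never the
default.

**Provenance.** Five cells of the example panel are substitutions from the
literature rather than measurements of the same extracts (tagged
`value[lit:citation]` in the fixture). Whether such values were
re-normalised to the same percent-of-control convention before printing is
not recorded in the source; the fixture stores them as printed. Because the
substitutions mix endpoints (COX-2/PGE2/leukotriene readings standing in for
COX-1/5-LOX), `score_panel(measured_only = TRUE)` masks them to missing, so
the sensitivity of every downstream result to the substitutions can be
quantified directly. With the mask on, A. dahurica, A. sinensis,
F. suspensa and S. baicalensis lose their beta scores.

## Clustering

Herbs are partitioned in a two-score plane by k-means (k = 3 by default,
following the three-cluster structure of the motivating analysis; no model
selection for k is performed — silhouette-style diagnostics would be
informational only).

Two solvers share one result type:

* `kmeans_exact()` enumerates every set partition of the points into at most
  k non-empty blocks (restricted-growth strings) with branch-and-bound
  pruning, in C++. Adding a point x to a block with m members and mean μ
  increases that block's sum of squares by m/(m+1)·‖x − μ‖², which makes the
  running objective a valid lower bound for pruning and gives the exact
  global minimum of the within-cluster sum of squares (wss). At n = 15,
  k = 3 this is an enumeration over 2,375,101 three-block partitions and
  runs in well under a second; the guard `exact_max_n = 18` keeps the search
  tractable. Ties are broken by the lexicographically smallest assignment
  vector over herbs sorted by id.
* `kmeans_lloyd()` is the standard Lloyd iteration with k-means++ seeding,
  best of `restarts = 100` restarts under one master seed. Assignment ties
  go to the lowest-index centroid; a cluster emptied during iteration is
  reseeded at the point farthest from its current centroid (this removes a
  positive term from the objective, so the repair never increases wss at the
  end of the step). Points are sorted by herb id before seeding, so results
  are invariant to input row order.

`cluster_scores()` picks the solver automatically (exact when the panel fits
the guard) and applies `canonical_labels()`: clusters are renumbered by
ascending centroid norm, ties by smallest member id. The motivation for
carrying an exact solver at all is that k-means results on small panels can
be initialisation-sensitive local optima, and the original SPSS-based
analysis recorded no initialisation details; exactness removes that
ambiguity at panel scale, and the test suite requires restarted Lloyd to
reach the enumerated optimum on the example panel and on 50 synthetic
panels.

**No feature scaling by default.** Both axes of each plane are magnitudes on
the same 0–200 percent-of-control scale, so the raw geometry is meaningful;
`scaling = "zscore"` exists for panels where the axes are not commensurate.

**The reduced (α, χ) plane.** On the 11-herb (α, χ) panel the exact optimum
does *not* isolate P. cocos, whereas the originally described grouping does.
`singleton_constrained_partition()` computes the best partition subject to a
forced singleton; on this panel it has wss 10635.2 against the global
optimum's 9967.4, i.e. the described grouping is a local optimum of the
k-means objective. The pipeline writes both partitions
(`clusters_alpha-chi.tsv` and `clusters_alpha-chi_described.tsv`) and takes
no position on which the original software produced; the package's own claim
is only the optimality property, which is what the tests assert.

## Trait association

The classical reading of cluster–character structure is a qualitative
overlay ("all members of the most active cluster are bitter and cold").
`cluster_overlay()` reproduces exactly that: per-cluster counts of collapsed
natures and flavors. The formal statistics in `test_trait_enrichment()` are
an **extension** beyond that overlay, and the written reports say so.

* Nature levels are kept at six ordinal levels on read (`cold` <
  `slightly_cold` < `neutral` < `slightly_warm` < `warm` < `hot`) and
  collapsed to cold/neutral/warm only for plotting and enrichment, matching
  the blue/grey/red overlay convention. The source material itself is
  inconsistent here (herbs described as "hot" in prose are "warm" in the
  character table), which collapsing also absorbs.
* A trait token is a flavor, a collapsed nature, or an action token matched
  against the action phrases through a small synonym map (`expel_wind` also
  matches "dispel wind", `tonify_qi` also matches "invigorate ... qi" and
  "move qi", etc.). The default tested set is every collapsed nature and
  flavor present plus the four action tokens singled out by the motivating
  analysis: `expel_wind`, `tonify_qi`, `clear_heat`, `remove_toxicity`.
* Each trait × cluster pair is tested by a two-sided Fisher exact test of
  the 2×2 in/out table; for a full 2×k table `exact_association_test()` uses
  the exact conditional test when the margins keep the table space below
  10⁶ tables and a seeded Monte-Carlo permutation p-value (10⁵ draws)
  otherwise. Degenerate margins return p = 1 with a warning. Odds ratios
  use a 0.5 continuity correction when any cell is zero.
* The Benjamini–Hochberg family is all trait × cluster pairs of one run.

On a 15-herb panel these tests are intentionally conservative: with the
example panel's margins even a perfectly pure 4-herb cluster does not
survive BH across the full default family. The tests' discriminating power
is demonstrated on synthetic panels (below), not on the example data.

## Synthetic panels

`generate_panel()` draws herbs around per-cluster centroids with independent
normal noise per endpoint, clipped at 0 (not truncated-renormalised — the
clip is simpler and keeps >100 values representable). Cluster memberships
are assigned round-robin, so a small panel can never lose a cluster by
sampling accident. Each herb carries its cluster's signature flavor and
nature with probability `trait_purity`, otherwise those of another
uniformly-chosen cluster; values are set missing independently with
probability `missing_rate`. Everything is reproducible from the spec's seed.

The default centroids (`paper_like_centroids()`: (40, 28), (133, 31),
(131, 105)) sit at the approximate cluster means of the example panel, so
synthetic tests exercise the same geometry as the real data: one compact
high-activity cluster, one eicosanoid-selective cluster, one diffuse
low-activity cluster.

What the generator deliberately does **not** emulate: correlated noise
across endpoints, assay-specific error structure, dose–response or IC50
behaviour, unbalanced cluster sizes, and trait sets richer than one
signature flavor/nature per cluster. Passing recovery tests therefore show
that the pipeline recovers clean Gaussian structure with coupled categorical
labels; they do not certify performance on real panels, where cluster shape
and trait coupling are messier.

Recovery experiments in the test suite use: 100 seeds at n = 30, k = 3,
spread 10 (minimum centroid separation ≈ 74, i.e. > 6 × spread), purity 1 —
requiring mean adjusted Rand index ≥ 0.95 against the true labels and a
BH-significant (q < 0.05) enrichment of every cluster's signature trait in
at least 95% of runs; 50 panels of 8–15 herbs for Lloyd-vs-exact optimality;
100 seeds per level at three spread levels (5, 15, 35) for the monotone
degradation check; and n = 10⁴ herbs for the binomial calibration of
`trait_purity`. These sizes make the whole suite run in well under a minute
while leaving the Monte-Carlo comparisons comfortable tolerances.

## Numerical and interface choices

* Rounding of scores: nearest integer, ties away from zero.
* Exact/Lloyd wss comparisons use absolute tolerance 1e-8; the exact
  solver's internal pruning uses the running objective itself, so no
  tolerance enters the enumeration.
* The adjusted Rand index is the standard pair-counting, chance-corrected
  form; two identical trivial partitions (everything in one cluster) define
  ARI = 1.
* Missing cells are written as `-`; `-`, empty and `NA` are accepted on
  read. Parsing is locale-independent (decimal point, no thousands
  separators).
* `run_pipeline()` writes only delimited text and JSON (plus PDF figures);
  reruns with the same config and seed are byte-identical on all text
  outputs, and each figure is accompanied by a TSV of its plotted
  coordinates, which is the determinism surface for graphics. The manifest
  records config, seed, md5 hashes of the inputs and package/R versions —
  enough to re-execute a run. A stage failure aborts with a stage-tagged
  error and removes the files already written by that run.

## Known limitations

* The α definition ambiguity is resolved by agreement with the printed
  scores, not by access to the original computation; both definitions are
  one switch apart.
* Enrichment p-values condition on the clustering, which was itself chosen
  to optimise separation in score space; on small panels they should be
  read as descriptive strength-of-association measures, not confirmatory
  tests.
* The exact solver is exponential in n (it is an enumeration); `exact_max_n`
  defaults to 18 and should be raised only with care.
* Meridian and free-text action fields are tokenized shallowly; no attempt
  is made to encode a full action ontology.
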