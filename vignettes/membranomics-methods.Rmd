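---
title: "Methods: enrichment, tree mining, quantification ratios and network statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment, tree mining, quantification ratios and network statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranomics)
```

## The sampling model

A membranome analysis treats the selected protein set (the `n` proteins of
a membrane-fraction proteome that match the reference database) as a draw
without replacement from a universe of `N` annotated proteins. For a
category with `A` universe members, the observed category count `a` is then
hypergeometric, and the enrichment statistic is the standardized count

$$z = \frac{a - nA/N}{\sqrt{n \frac{A}{N}\left(1-\frac{A}{N}\right)\frac{N-n}{N-1}}}.$$

Positive `z` means over-representation. The significance rule is
`|z| >= 2`, inclusive at the boundary, corresponding to an approximate 95%
confidence band; no multiple-testing correction enters the rule itself.
Exact hypergeometric tails and Benjamini–Hochberg q-values are emitted as
supplementary columns for users who want them, clearly separated from the
classification rule.

**Variance convention.** The default variance carries the finite-population
correction `(N−n)/(N−1)`, which is the variance of the hypergeometric
distribution the model assumes. Because some legacy ontology tools
standardized with the plain binomial variance instead, `zscore()` and every
caller expose `variance = "binomial"` to drop the correction. With
`N >> n` the two agree; at membranome scale (`n/N` around 5–10%) the
hypergeometric z is a few percent larger in magnitude. We default to the
convention consistent with the stated sampling model rather than to any
particular historical implementation.

**Degenerate categories.** The count invariants (`a <= min(n, A)`,
`n - a <= N - A`) force `a` to equal its expectation whenever the variance
vanishes (`A = 0`, `A = N`, or `n = N`), so the zero-variance case returns
`z = 0`; a signed-infinity marker with a warning remains as a defensive
path for callers who bypass validation. This keeps whole-table runs total:
an identity membranome scores 0 everywhere rather than erroring.

**Tails.** `P(X >= a)` and `P(X <= a)` are computed in log space via the
regularized routines underlying `stats::phyper`; both tails include the
point mass at `a`, so they sum to at least 1. The test suite checks them
against an independent factorial-ratio (log-gamma) summation to 1e-12
relative error over all small universes and thousands of random tuples.

## True-path propagation and "general categories"

Annotation tables arrive as raw protein-to-term records. Before any
counting, every protein's term set is closed under ancestry (the true-path
rule), after which `A(parent) >= A(child)` holds on every edge. `is_a`
edges always propagate; `part_of` propagation is a flag, default on, the
common ontology convention. Records whose term is unknown or obsolete are
dropped and counted in a parse report rather than raised as errors —
database-version drift is a fact of life in annotation data (the motivating
dataset matched only 76% of its proteins) and must be survivable.

"General categories" — the top-level bars of a classical enrichment chart —
are defined as the direct children of the namespace root, in
identifier-sorted order. This needs no knowledge of any specific tool's
leveling scheme and reproduces the top-level category lists such charts
display.

## Recursive tree mining and "actual enriched" terms

The miner starts at each general category and descends the DAG. A node's
children are visited when

1. the node is significantly enriched (always expanded),
2. the node's `z` exceeds the policy expansion rule (default `z > 0`), or
3. the node is on the user's force-expand list.

The default rule mirrors the practice of expanding categories with positive
scores; the force list exists because real analyses deliberately descend
into depleted branches (e.g. finding a strongly enriched phosphate-related
transport term two levels under a mildly depleted ion-transport parent).
Both behaviors are asserted in the tests: without forcing the deep term is
missed, with forcing it is recovered.

"Actual enriched" is formalized as a terminality condition: a visited,
significantly enriched term none of whose visited children is itself
enriched — the deepest enriched refinement along its path. Multi-parent
terms are visited once per path but deduplicated in the reported set.
Singleton categories (`A` below `min_A`, default 2) are reported but
flagged low-support because `z` is unstable there. `max_depth` defaults to
10; real analyses rarely mine past four levels.

Custom categories (e.g. a manually curated mechanotransduction set absent
from public ontologies) are injected as direct children of the namespace
root with their protein lists added to the universe annotations, and then
scored like any other term.

## P/H quantification ratios

The quantitative membrane-enrichment measure is the ratio of a protein's
normalized spectral index in the membrane fraction (P) to that in the
whole-tissue homogenate (H). Conventions:

* finite ratio `> 1`: membrane-enriched; `< 1`: depleted;
* detected in P only (`sin_H = 0`): infinite ratio, class `PM_only`;
* detected in neither, or ratio exactly 1: `undetermined`. The definition
  covers only strict inequalities, and we refuse to silently side with
  either class at equality.

"Detected in both fractions" predicates operate on finite, defined ratios,
so infinite-ratio records never match a finite bound — this is what makes
the packaged 28-record translation-factor table yield exactly 7
membrane-enriched factors. Location strings are split on `;` and `,`,
case-folded and trimmed; `undecided`, `unknown` and `NA` map to
unannotated. The two packaged quantification tables are transcriptions of
published tables; visible text-extraction artifacts (column bleed between
the location and staining columns) were normalized during transcription,
and one internally inconsistent printed ratio (416.78 against a narrative
range of 0.5–5) is preserved as printed and flagged in the file header.

## Network statistics

Interaction data arrive as plain edge lists — the package ships no
proprietary interaction content. Graphs are simple and undirected
(duplicate edges collapsed, self-loops dropped with a warning); a directed
expression-control flag is carried as annotation but ignored by all
statistics. Merging is a deduplicating union with first-wins attribute
conflict resolution, so merging a graph with itself is the identity.

The network score is `−log10` of the right-tailed Fisher exact
(hypergeometric) probability of observing at least `focus_count` input
molecules in a network, given the network size, the number of eligible
input molecules, and the knowledge-base universe size. The universe and
eligible totals are explicit inputs: they are properties of the reference
database, not something the package can guess. The score is zero exactly
when the tail probability is 1 and is monotone in the focus count by
construction.

Quantification overlays color nodes `enriched_red` (finite ratio above 1,
or membrane-only), `depleted_green` (below 1), and `absent_white`
otherwise; `undetermined` records carry no directional evidence and are
deliberately mapped to the absent class rather than given a fourth color.
Intensity is `|log2(ratio)|`, with membrane-only nodes at the maximum.
Subnetwork extraction is a strict induced subgraph — only direct
interactions between retained molecules survive, and manually augmented
molecules enter with no edges.

## The synthetic world

The generator states one world and the tests live in it:

| parameter | default | why |
|---|---|---|
| `N` | 20000 | scale of a public annotation universe |
| `n` | 1800 | scale of a deep plasma-membrane proteome |
| ontology | depth 3, branching 4 | 85 terms, enough structure for multi-level mining at desk scale |
| leaf annotation density | 0.05 | mid-sized categories (~5% of universe) |
| `log2_enrichment_mean` | 1 | a twofold average membrane enrichment for true membrane proteins |
| `log2_enrichment_sd` | 0.5 | biological + technical spread of label-free ratios |
| `dropout_H` | 0.1 | ~10% of membrane proteins undetected in homogenate, producing infinite ratios |
| modules | 20/16/16, `p_within` 0.3, `p_between` 0.02 | function-defined dense clusters against a sparse background |

Tests and the acceptance suite run the same world scaled down to
`N = 3000, n = 300` for speed; the planted term covers ~5% of the universe
with sampling odds 5. Enrichment planting is multiplicative on sampling
weights — the protein's weight is the product of the odds of the terms it
carries — which makes the planted alternative a noncentral hypergeometric
draw with a well-defined power target rather than an ad-hoc swap. Each
generator draws from its own RNG stream derived from the master seed by a
stable label, so adding a generator never perturbs existing outputs and
every artifact is byte-identical under a fixed seed.

What a green synthetic test establishes: the statistics, the propagation,
the miner's traversal logic, and the generators' own contracts. What it
does not establish: anything about real annotation quality, identifier
mapping across databases, or the content of curated interaction knowledge
bases — real analyses stand or fall on those inputs.

At the test scale, the planted term is recovered as an actual-enriched
term in 99% of 100 seeded replicates, and in a matched null world the
`|z| >= 2` rule flags 4.5% of terms — consistent with its nominal ~5%
two-sided level; the acceptance suite freezes that calibration and checks
against it.

## Numerical and design choices

* All orderings (term tables, reports, TSV output) are identifier-sorted,
  so every artifact is reproducible byte-for-byte; manifests record MD5
  checksums and contain no timestamps.
* Full precision everywhere; rounding (e.g. edge/node ratio 3.2) happens
  only in rendered, human-readable views.
* Classification thresholds are inclusive (`>= 2`, `<= −2`) per the stated
  rule.
* Protein identifiers are opaque, case-sensitive strings; cross-database
  mapping is the caller's concern.
* The exhaustive tail-oracle check is exhaustive for small universes
  (`N <= 25` and `N = 60`) and randomized (2000 tuples) up to `N = 200`,
  keeping the suite within its runtime budget while covering every support
  boundary case.

## Known limitations

* The miner reports a tree per general category even though the ontology
  is a DAG; multi-parent terms may be visited repeatedly (deduplicated in
  the reported set), which is the standard chart-oriented reading, not a
  graph-theoretic summary.
* No GSEA-style rank statistics, no permutation nulls — the statistic is
  count-based by design.
* Network analyses compute statistics on user-supplied graphs only; there
  is no pathway reconstruction and no bundled interaction knowledge.
* The quantification side consumes spectral-index values; it does not
  compute them from spectra.
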