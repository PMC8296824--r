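---
title: "Methods: CGPD-tetramer inference, network summaries, and regulatory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGPD-tetramer inference, network summaries, and regulatory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpdnet)
```

## Scope

`cgpdnet` implements two analysis arms that share a common question —
what do pesticide residues on cannabis plausibly do to patients using
cannabis for neurological conditions — but operate on different inputs:

1. a *toxicogenomic* arm that constructs chemical–gene–phenotype–disease
   (CGPD) tetramers from curated pairwise interaction tables in the
   Comparative Toxicogenomics Database (CTD) flat-file dialect, builds
   the tetramer-weighted bipartite chemical×gene network, and summarizes
   gene connections per biological function with epilepsy-gene overlap;
2. a *regulatory* arm that compares pesticide action levels for cannabis
   across jurisdictions (medians, fold-ranges, comparison with reference
   tolerances) and tabulates qualifying-condition categories for
   medical-cannabis programs.

A synthetic-data generator emits inputs for every stage with
machine-readable ground truth, so the entire pipeline is testable
without network access or external databases.

## The CGPD-tetramer model

A CGPD-tetramer is a quadruple $(c, g, p, D)$ of a chemical, a gene, a
phenotype, and a fixed disease endpoint $D$ (default `MESH:D012640`,
seizures).  The quadruple is asserted only when **all five** curated
evidence lines exist:

| evidence line    | pair      |
|------------------|-----------|
| chem–gene        | $(c, g)$  |
| chem–phenotype   | $(c, p)$  |
| gene–phenotype   | $(g, p)$  |
| chem–disease     | $(c, D)$  |
| gene–disease     | $(g, D)$  |

The construction is a pure set conjunction: `build_tetramers()`
collapses each evidence table to its distinct pairs (duplicate curated
records count once), intersects the five memberships, and returns every
completed quadruple.  Consequences that the test suite asserts as
properties:

* **monotonicity** — adding evidence rows can only add tetramers;
* **permutation invariance** — row order of the inputs never matters;
* **idempotence** — re-running on the same inputs gives identical
  output;
* **oracle equivalence** — on small instances the result equals a
  brute-force triple loop over all (chemical, gene, phenotype)
  combinations.

Entity identifiers are normalized to `NAMESPACE:accession` keys
(namespaces upper-cased, gene symbols upper-cased, whitespace trimmed);
keys split on the *first* colon only so accessions containing colons
survive a round trip.  Output ordering is deterministic (lexicographic
by accession), so equal inputs give byte-identical outputs.

Chemical scope (e.g. "insecticides only") is applied by filtering the
chemical axis with a chemical-class table *before* conjunction; scoping
is equivalent to post-hoc filtering of the tetramer set, and a test
asserts that equivalence.

## Bipartite network and weighted degree

`build_edge_list()` projects the tetramer set onto chemical×gene pairs;
the weight of edge $(c, g)$ is the number of tetramers containing that
pair.  Because every tetramer contributes to exactly one edge, three
conservation identities hold exactly and are asserted in the
acceptance suite:

$$\sum_{\text{edges}} w = T = \sum_{\text{chemicals}} \deg_w(c)
  = \sum_{\text{genes}} \deg_w(g),$$

where $T$ is the tetramer count and $\deg_w$ is weighted degree (sum of
incident edge weights, `weighted_degree()`).  A chemical's weighted
degree equals its per-chemical tetramer count.  Graphs export to
GraphML (via `igraph`, with partition, function category, and weighted
degree as vertex attributes) or to a plain CSV edge list.

## Per-function gene summary

`summarize_by_function()` reproduces the logic of a per-function gene
connection table: for each (function, gene) pair it reports the number
of distinct insecticides connected to the gene, the number of
insecticide tetramers, and the number of cannabinoid tetramers; genes
on the epilepsy panel are flagged and retained even at zero counts.
Per-function totals count *distinct* insecticides across the function's
genes (a chemical touching three genes counts once), while tetramer
totals are sums of the per-gene cells:

$$\text{total tetramers}(f) = \sum_{g \in f}
  \big(\text{insecticide tetramers}(g) + \text{cannabinoid
  tetramers}(g)\big).$$

The shipped fixture `gene_connections_published.csv` carries published
per-gene cells whose totals (183, 45, and 46 tetramers for the
oxidation–reduction, cholinergic, and neuropeptide functions) the
aggregation operators must reproduce exactly.

## Regulatory statistics

`pesticide_stats()` computes per-pesticide summaries across
jurisdictions after collapsing exact duplicate records:

* **median** — sample median of distinct records; an even count takes
  the mean of the two middle values;
* **fold-range** — maximum divided by the *effective* minimum.  A
  zero-tolerance record (action level 0 ppm) substitutes its limit of
  quantitation (LOQ) in the denominator when one is given and is
  excluded from the denominator otherwise; the reported minimum level
  remains 0.  With no positive denominator the fold-range is `NA` and
  such pesticides are excluded (with a message) from `top_variation()`;
* **median-to-reference ratio** — the median action level divided by
  the pesticide's lowest reference tolerance, when a tolerance table is
  supplied; `mean_fold_above_reference()` averages these ratios
  arithmetically (default) or geometrically.  The averaging method is
  an explicit flag because an aggregate "fold above tolerance" is not
  well-defined without it.

Fold-ranges are invariant under unit-preserving rescaling of all
levels, and all statistics are permutation- and duplication-invariant;
both are asserted as properties.

## Qualifying conditions

Condition names are normalized (lower-cased, punctuation stripped,
whitespace collapsed) and mapped through an editable condition →
category → domain table, validated so that each condition has one
category and each category one domain.  Coverage counts each
jurisdiction at most once per category; domain totals count distinct
conditions per disjoint domain, so the grand total is the sum of the
domain counts.

## Synthetic-data generator

The generator is designed so that planted quantities are realized
*exactly*, not approximately:

* **Tetramers** (`simulate_ctd_tables()`): planted quadruples are
  placed one at a time; each candidate is accepted only if adding its
  five evidence lines completes no quadruple beyond the planted set
  (checked incrementally, since a new completion must involve a new
  pair).  Draws are random with a bounded retry budget, after which an
  exhaustive scan of the admissible gene×phenotype grid runs before the
  configuration is declared infeasible.  Shared genes/phenotypes
  between the insecticide and cannabinoid arms are realized exactly via
  per-class queues of entities that must still be used; while a class
  has slack, an awkward queue entity may be deferred to a later
  placement.  Decoys are near-tetramers on fresh flanking chemicals and
  genes missing exactly one uniformly chosen evidence line; building
  them on fresh entities (rather than deleting lines from shared
  entities and repairing side effects) guarantees by construction that
  a decoy can never complete another quadruple.  Before emission a
  brute-force enumeration verifies that the tables realize exactly the
  planted set — the generator *proves* its own ground truth.
* **Action levels** (`simulate_action_levels()`): per-pesticide levels
  are constructed, not sampled — the planted minimum, maximum, and
  median are placed literally (an even count places the median value
  twice in the middle) with log-spaced interior values, so the planted
  statistics are recovered bit-exactly.
* **Reference tolerances** (`simulate_reference_tolerances()`):
  lognormal ratios are rescaled so the chosen mean (arithmetic or
  geometric) of median-to-tolerance ratios equals the target exactly.
* **Conditions** (`simulate_conditions()`): conditions are assigned
  round-robin over a sampled jurisdiction subset so the planted
  per-category coverage and domain totals are exact.

The generator defaults are the study conditions: 24 chemicals (22
insecticides in six classes plus two cannabinoids), 57 genes, 146
phenotypes, 175 planted tetramers (150 insecticide / 25 cannabinoid), 8
shared genes, 4 shared phenotypes, and a condition specification with
disjoint domain sizes 30/9/17 (56 conditions) across 31 jurisdictions.
All randomness flows through a single mandatory `seed` argument;
identical seeds give byte-identical output files.

## Numerical conventions

* medians follow the standard sample-median convention
  (`stats::median` semantics, implemented over distinct records);
* fold computations use exact ratios of the input values — no rounding
  is applied before ratios;
* JSON output is written with full precision (`digits = NA`);
* per-jurisdiction mean condition counts are reported rounded to a
  configurable number of digits (default 0).

## Limitations

* The full-database outputs of a CTD analysis depend on the database
  release; they are not reproducible at desk scale and are treated as
  external-reference expectations only.  All shipped fixtures are
  either printed table cells or synthetic.
* The shipped action-level and tolerance tables are small illustrative
  fixtures anchored to published endpoints, not a compilation of any
  jurisdiction's current regulations.
* When a reference source lists many tolerances per pesticide, the
  package takes the supplied "lowest tolerance" as given and does not
  resolve commodity choice.

## Problem sizes

The design targets desk scale: tens of chemicals, tens-to-hundreds of
genes and phenotypes, and planted tetramer counts up to a few hundred.
Generation at default size takes roughly a second; a full synthetic
end-to-end run (simulate → build-tetramers → network → pathways)
completes well under two minutes on one CPU, and the brute-force oracle
comparisons used in testing are limited to instances with at most 50
entities per axis.
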