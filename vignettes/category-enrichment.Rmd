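---
title: "Category-level GO enrichment: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-level GO enrichment: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catego)
```

This vignette documents the statistical models behind `catego`, the
conventions it adopts where the field has more than one, and the design
decisions that were genuinely open. It is the reference for *why* the
package behaves as it does; the README shows *how* to use it.

## The category model

A **category** is a named set of GO terms representing one broad
biological theme. Categories may span all three GO namespaces, and member
terms must form an *antichain* of the GO DAG: no member may be an ancestor
or descendant of another member (`validate_category()` reports every
violating ordered pair). The rationale is counting: category membership of
a gene is decided by whether any of its annotations falls into the
*descendant closure* of a member term, and if one member were an ancestor
of another, the genes below the deeper term would be reachable through two
members at once — the category's gene count would silently depend on
redundant structure rather than on biology.

Membership propagation up the DAG (`include_descendants = TRUE`) is the
default everywhere. High-level category terms are rarely used for direct
annotation — annotators prefer specific terms — so without propagation the
categories of a specifically-annotated genome would be nearly empty. The
flag is exposed because the choice is a modelling decision, not a law:
with propagation off, only direct annotations to the member terms count.

Which relations form the hierarchy is equally a choice. `parse_obo()`
treats `is_a` and `part_of` as hierarchy edges by default, which is the
GO-slim convention; `relations = "is_a"` restricts to the subsumption
backbone. `regulates`-family relations are deliberately not supported:
propagating gene membership across regulation would conflate "is an X"
with "controls an X".

The shipped file `inst/extdata/default_categories.tsv` maps thirteen
broad, cross-species category names onto generic GO-slim-level term ids.
It is a reconstruction curated for this package and marked as data, not
code: any serious analysis should review or replace it, and
`load_categories()` accepts the same TSV (or JSON) from the user.

## The Fisher branch (candidate gene lists)

With background $N$ (annotated genes, optionally restricted by the user),
sample $n \subseteq N$, category background count $K$ and category sample
count $k$, the raw p-value is the hypergeometric upper tail
$P(X \ge k)$ — a **one-sided over-representation** test. The paper-family
of tools this workflow belongs to speaks only of "enrichment";
under-representation is out of scope and would need a different reporting
convention, so one-sidedness is fixed and documented rather than
configurable.

Adjustment is Benjamini–Hochberg, and the **family is the set of
categories actually tested in one run** — categories with $K = 0$ are not
testable (reported separately, `attr(res, "not_testable")`) and do not
consume multiplicity. The per-term zoom is unadjusted by design: it is a
decomposition of one already-significant category, not a new screen, and
its output therefore has no `p_adj` column at all rather than an empty
one.

The effect size is the normalized term-frequency $k/K$: unlike $k/n$ it is
comparable across categories of very different sizes, which is what the
heat-map view needs.

**Harmonization.** `sample ⊆ background ⊆ annotated genes` is enforced,
not assumed: background genes without annotation are dropped from $N$,
sample genes outside the background are dropped from $n$ with a warning,
and the counts of both removals are kept. Dropping (rather than aborting)
keeps multi-dataset workflows usable when lists come from slightly
different identifier universes; the warning keeps it honest.

## The Mann–Whitney branch (measured gene lists)

For a named vector of finite measures, each category's in-genes are
compared against **all other measured, annotated genes** with a two-sided
Mann–Whitney U test. Two-sidedness is deliberate: a category can
concentrate in either tail, and the direction is read from the sign of the
effect rather than from the test.

The effect is the **delta rank**: mean pooled rank (ascending, average
ranks on ties) of in-category genes minus mean rank of the rest. This is
the convention of the rank-based GSEA lineage this workflow follows; the
sign is positive when the category sits in the high measures. Delta ranks
are invariant under any strictly monotone transform of the measures, which
the suite asserts.

**Exactness threshold.** For pooled sizes $n_1 + n_2 \le 16$ the p-value
is computed by full enumeration of all $\binom{n_1+n_2}{n_1}$ labelings of
the observed values (so ties are handled exactly, with the symmetric
two-sided deviation $|W - E[W]|$); larger problems use the tie-corrected
normal approximation with continuity correction, which at the category
scale (hundreds of genes) agrees with the exact null to well below any
decision threshold. The bound is on the *total* because the enumeration
cost is $\binom{n}{n_1}$, which is what actually limits exactness; it is
configurable via `mwu_unit(exact_limit = )`.

## Set operations and the result store

Up to four named gene sets are partitioned into Venn classes by exact
membership signature (a string of 0/1 flags in collection order); the
partitions are disjoint and cover the union by construction, and any union
of partitions can become the **iterative background** of the next run —
enrichment relative to another dataset instead of the full annotation.

The result store is a functional, append-only session object: each
analysis contributes one column (label, test type, background label,
per-category results), labels are suffix-deduplicated, and appending never
mutates earlier columns. The heat-map matrix is laid out with rows in
first-seen category order — rows match across species by category *name*,
which is the point of shared categories — and a cell is `NA` (not zero)
when the requested measure is undefined for that column's test (delta rank
for a Fisher column, term-frequency for an MWU column) or the category was
not tested there. `NA` survives TSV export as a literal sentinel, so mixed
stores export losslessly. Stores serialize to JSON; provenance includes
paths and labels but no timestamps, so re-running a session reproduces
byte-identical files.

## Networks

The interaction graph is an undirected simple graph per interaction kind
(physical/genetic, from the experimental-system-type column of
BioGRID-style tables); repeated observations collapse into an edge
multiplicity. Self-loops are dropped at parse time.

**Connectors.** A connector candidate is a non-selected gene lying on at
least one shortest path (breadth-first, in the complete graph) between two
selected genes, detected via the distance identity
$d(s,v) + d(v,t) = d(s,t)$ over per-source BFS maps. *All* shortest paths
count, not an arbitrary first one — which path BFS happens to find first
is an implementation accident, not information. The budgeted selection
ranks candidates by the number of selected pairs whose shortest-path
distance they realize, ties broken lexicographically by gene id; the
ranking rule is this package's own convention (any fixed, documented rule
would do — what matters is determinism).

**Semantic edge lengths.** The length of an edge between two genes is the
mean GO-graph shortest-path distance over all pairs of their annotated
terms. Unreachable term pairs (different namespaces have no connecting
structure; no artificial super-root is invented, since it would distort
every cross-namespace distance by a constant) are *excluded from the
mean* rather than penalized — a penalty of "max + 1" was rejected because
it grows with ontology size and would dominate the mean for genes with
multi-namespace annotations. If no pair is reachable the length is
missing. A floor of `epsilon = 0.01` keeps identically-annotated genes at
a positive, drawable length.

**Receptor–ligand pairing.** Records with one endpoint in each dataset
qualify when *both* endpoints carry a receptor or ligand annotation
(descendant-expanded). The literal reading admits receptor–receptor
pairs; because the signalling interpretation suggests complementary
roles, `strict = TRUE` demands one receptor and one ligand. Both
behaviours are exposed and neither is asserted as the intended one. The
historical receptor id (GO:0004872) is obsolete in modern GO releases;
`resolve_term()` follows `replaced_by` chains, and both role term ids are
overridable.

## The synthetic fixtures: what they do and do not show

The generator builds, deterministically per seed: a rooted
biological-process DAG (b-ary tree skeleton, ~10% random second parents,
85%/15% `is_a`/`part_of`), a small fixed molecular-function block carrying
the receptor/ligand role terms plus an alias and two obsolete terms, an
annotated population, category definitions, candidate samples, measured
lists and a TAB3-style interactome with planted paths and planted
receptor–ligand pairs. Defaults are the study scale: 1,000 genes, 300
terms, 2–6 annotations per gene, planted category of 100 (Fisher) or 50
(MWU) genes, sample of 100.

Planted-signal construction: with fold $f$, each planted-category gene
enters the sample independently with probability $f \cdot n/N$ (expected
overlap $K f n/N$ — 50 at the defaults), the rest drawn uniformly;
$f = 1$ degenerates to uniform sampling without replacement, making the
null *exactly* hypergeometric. The measured list is standard normal with
the planted genes shifted by a configurable number of SDs. Categories are
assembled from sibling groups with two structural guarantees that real
GO-slim category sets share: each category's descendant closure holds at
least ~8 terms (a category that annotates one or two genes is not a
category, and its rank statistics would be pure noise), and closures are
pairwise disjoint (a specific term never feeds two categories).

What passing on these fixtures shows: the counting, testing, adjustment,
partitioning and graph machinery is correct against independent oracles,
and the planted effect sizes are recovered with the advertised
sensitivity and calibration. What it does not show: robustness to the
shapes of real data — GO's actual topology (deep, heavily multi-parent,
very uneven annotation density), inter-gene annotation correlation,
identifier mess, or scale-free interactomes. The generator is a
correctness instrument, not a realism benchmark.

## Calibration and numerical notes

* The Fisher p-value at fixture scale is **discrete** (the hypergeometric
  support at $N=1000, K=100, n=100$ has atoms with mass up to ~0.13), so
  its distribution under the null can never be within Kolmogorov distance
  0.1 of the continuous uniform between atoms. The calibration check
  therefore compares the empirical p distribution against the *exact null
  law of the p-value* at its atoms (where super-uniformity holds with
  equality). The MWU p at 1,000 pooled genes is effectively continuous
  and is compared against U(0,1) directly.
* Benjamini–Hochberg is delegated to `stats::p.adjust`; the exhaustive
  and randomized oracle checks in the suite use an independently coded
  definitional step-up. BH is *not* idempotent (re-adjusting an adjusted
  vector changes it), so no such property is claimed.
* `phyper` is used for the Fisher tail; the suite verifies it against
  exact integer-arithmetic enumeration for every valid table with
  $N \le 30$ (all binomial coefficients involved are below $2^{53}$, so
  the double-precision enumeration is exact).
* BFS frontiers (terms and genes alike) are expanded in sorted-identifier
  order, making every traversal, tie-break and export byte-reproducible.
* Tests and the acceptance script run at deliberately desk-sized problem
  scales — ontologies of tens to hundreds of terms, populations of
  hundreds to a thousand genes, 100–200 replicates per simulation claim —
  chosen so the whole suite completes in minutes while keeping the
  binomial/KS noise of each claim well inside its margin.

## Known limitations

* No evidence-code filtering and no identifier cross-mapping: the
  annotation table is taken at face value, and gene ids must match
  between lists, annotations and interaction tables.
* Under-representation is not reported (one-sided Fisher by design).
* The per-term zoom inherits the category's membership convention; terms
  annotated only above the category's members are invisible to it.
* Cross-namespace semantic distances are undefined rather than modelled;
  genes annotated in disjoint namespaces get missing edge lengths.
* The connector ranking is one reasonable convention among several; with
  a tight budget, different rules can pick different (equally valid)
  connector sets.
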