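---
title: "Testing partition-specific phylogenetic signal under maximum parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing partition-specific phylogenetic signal under maximum parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MorphoMask)
```

## The question the package answers

Morphological phylogenetics of fossil groups is often dominated by
cranial characters, because skulls preserve and are described far more
often than postcrania. When postcranial characters are finally added to
a matrix, a focal clade can move: in latest-Cretaceous European
eusuchians (allodaposuchids), adding 38 postcranial characters to a
189-character matrix pulls the family from a basal eusuchian position
into crown Crocodylia. The question is whether such a shift is really
carried by the partition, or by incidental taxon additions.

MorphoMask operationalises the test as a battery of parsimony analyses
on controlled variants of one matrix:

* **control** — the matrix without the newly added taxa;
* **full** — the matrix as compiled;
* **masked** — the same matrix with the partition under test set to
  missing (`?`) in the focal taxon set, so those taxa are scored by the
  remaining characters only;
* **transferred** — partition scores moved from the taxa that preserve
  them onto other focal taxa, with the donors removed, isolating the
  partition's signal from the identity of its carriers.

If the placement classification of the focal clade differs between the
full and masked analyses, the partition carries its own signal for that
placement.

## Parsimony machinery

Characters are discrete, unordered and equally weighted; cells are
state *sets* (singletons, polymorphisms such as `[01]`, or missing).
Tree length is computed by the Fitch downpass — intersect child sets,
or union them and add a step — with missing cells initialised to the
character's full observed alphabet and polymorphic cells to their set.
State sets are bitmasks and the scorer is compiled, so a full-matrix
rescore costs microseconds at the problem sizes the package targets
(tens of taxa); branch swapping re-scores candidate trees outright
rather than maintaining incremental partial optimisations, which keeps
the kernel simple and is comfortably inside the same performance
envelope at these sizes.

Searches follow the classic heuristic protocol: random addition
sequences (taxa inserted in seeded random order at the attachment edge
of minimum incremental length, ties to the lowest edge index) followed
by branch swapping — NNI, SPR or TBR (default) — accepting strict
improvements first-found, with deterministic move ordering so a seed
fully reproduces a run. At a local optimum the plateau is explored
breadth-first and up to `hold` equally short trees are retained;
equally best trees are pooled across replicates and deduplicated by
unrooted topology. The desk-scale default is 50 replicates with an
early stop after 20 unproductive replicates; a published-protocol-sized
run (1000 replicates, no early stop) is a `searchConfig()` away. The
count of equally parsimonious trees is *not* a stable quantity across
implementations — it depends on the collapsing rule, hold limits and
swap order — so downstream summaries rest on best length, consensus
topology and index values instead.

Per-character bounds come from the matrix alone: the minimum steps
`m_i` is the size of the smallest state set hitting every scored cell
minus one (polymorphisms are resolved favourably; found by exhaustive
subset search over the small per-character alphabet), and the maximum
`g_i` is the number of scored taxa minus the best achievable count of
the most frequent state. The ensemble consistency index is
CI = sum(m)/S and the retention index RI = (sum(g) − S)/(sum(g) − sum(m)).
Both include parsimony-uninformative characters by default (the
convention of the common parsimony programs); a flag switches to the
informative-only variant, since published values rarely state which
convention produced them.

Support comes from character bootstrap (resampling implemented as
integer character weights, each pseudoreplicate searched with a reduced
budget and summarised by strict consensus) and Bremer decay, computed
by a suboptimal-retention search: the TBR neighbourhoods of the pooled
optimal trees are expanded breadth-first, keeping every distinct
topology within `maxExtra` steps of the optimum, and each consensus
clade's decay is the smallest extra length at which a retained tree
lacks it. On small instances this matches exhaustive enumeration (the
test suite checks it); on large ones it is a lower-bounded estimate of
the true decay, as retention searches always are.

## Exact reconstruction sets and synapomorphies

Ancestral state sets are computed exactly, not sampled: a uniform-cost
dynamic program (inside costs by a downpass, outside costs by a
preorder pass) yields, for every node, the set of states attainable in
*some* most-parsimonious reconstruction. A change to state *d* on a
clade's stem is **unambiguous** when every reconstruction of every
supplied tree asserts it, which is decided by re-running the downpass
with node-state clamps: the change occurs in all reconstructions iff
forcing the clade node away from *d*, or its parent to *d*, both cost
extra. Characters missing across the whole clade can never produce a
stem change and are never reported. Reversals inside the clade appear
as a second change record on the nested branch. Polymorphic terminals
are satisfied by any member state, so no change is forced into a leaf
whose set contains the ancestral state.

## Placement classification and monophyly

The focal clade's position is classified against three named anchor
sets. It is `crown_crocodylian` when the smallest clade containing the
focal taxa plus the crown-side anchors excludes every gavialoid anchor;
`basal_eusuchian` when the smallest clade containing the focal taxa
plus the hylaeochampsid anchors excludes every crown-lineage anchor, or
when the focal taxa fall wholly outside the clade spanned by the
crown-lineage anchors; otherwise `unresolved` — consensus polytomies
that merge the relevant spans deliberately refuse a call rather than
guessing. The classification only uses smallest-containing-clade
queries, so it is invariant to rerooting along the outgroup edge.

Monophyly of a named tip set is the standard convexity trichotomy: a
rooted clade is `monophyletic`; otherwise the set is `paraphyletic`
when, within the smallest containing clade, the set and its complement
occupy vertex-disjoint Steiner subtrees, and `polyphyletic` when those
subtrees interlock.

## The simulator and what the tests do (and do not) show

`simulateMatrix()` evolves unordered characters root-to-tip on a given
topology with per-branch change probability `1 − exp(−b·r)` (branch
length `b` in expected changes, per-partition rate multiplier `r`), a
deliberate simplification of a full rate-matrix process that keeps
ground-truth change counts exact and interpretable. Planted marker
characters change exactly once, on the stem of a named clade, so they
are guaranteed homoplasy-free synapomorphies with known identity.
Missingness is applied per cell with a per-taxon probability,
optionally restricted to one partition — the fragmentary-fossil
pattern of taxa known only from skulls.

`makeConflictScenario()` packages the study design: 16 taxa comprising
an outgroup, two hylaeochampsid-like anchors, two gavialoid-like
anchors, two further crown anchors, a crown ladder and a focal clade;
a base topology with the focal clade inside the crown and a conflict
topology with it attached basally. Defaults, fixed once as the
package's study conditions: 25 "postcranial" characters carrying 12
focal-stem markers for the crown attachment, 40 "cranial" characters
carrying 6 focal-stem markers for the basal attachment, backbone
markers cycled over each partition's generating clades — two deep
where the slot budget allows, so no single homoplastic noise character
can tie a backbone clade (the cranial partition covers the clades
shared by both topologies, keeping its conflict confined to the focal
attachment) — and the remainder evolved as noise with one expected
change per character (tree length normalised to 1; roughly a quarter
of noise characters end up homoplastic). The negative control moves
the cranial focal markers onto the base topology, removing the
conflict while keeping matrix dimensions identical. Scenario analyses
use 8 addition replicates holding 20 trees, enough to saturate the
small most-parsimonious-tree plateaus these matrices produce.

These conditions emulate *signal structure*, not realism in rates:
real morphological matrices have far more homoplasy (ensemble CI well
below 0.5), correlated characters, and non-random missingness. Passing
the recovery and conflict tests therefore shows the machinery is
correct and the experimental logic sound — it does not show that any
real partition's signal is as clean as the planted one.

## Numerical and degenerate-input choices

* `?` and `-` both mean missing; under unordered parsimony with this
  engine the two are indistinguishable, matching common practice for
  these files.
* Characters with no observed state contribute zero to S, sum(m) and
  sum(g); RI is reported as `NA` when sum(g) = sum(m).
* Character ids are 1-based everywhere a user sees them.
* Ordered (`ccode +`) or differentially weighted characters in an
  input file are a hard error, not a silent reinterpretation.
* Ties in stepwise addition and branch swapping break to the lowest
  edge index; all stochastic choices flow from explicit seeds, so every
  analysis is reproducible from its configuration alone.
* Trees are `ape::phylo` objects rooted on the designated outgroup
  (the root's first child); comparisons that must be rooting-free
  (deduplication, RF) use unrooted bipartitions.

## Known limitations

* No ordered/Wagner characters, step matrices, implied weighting or
  continuous characters.
* Bremer values from retention searches are exact only when the
  retained pool saturates the near-optimal neighbourhood; the cap
  parameters trade completeness for time on large matrices.
* The search is the classic replicates+TBR protocol; none of the
  "new technology" strategies (ratchet, sectorial searches, fusing)
  are implemented, so very large matrices may need generous replicate
  budgets.
* Exact most-parsimonious-reconstruction enumeration is per character
  and assumes few states (morphological 0–2 coding); it would be slow
  for characters with many states.
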