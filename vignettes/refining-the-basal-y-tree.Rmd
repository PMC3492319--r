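---
title: "Phylogenetic mapping of Y-chromosome markers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic mapping of Y-chromosome markers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ytreemap)
```

## The problem

The male-specific region of the Y chromosome (MSY) does not recombine, so
every biallelic variant on it marks a single point in one shared genealogy.
Under the unique-event-polymorphism (UEP) assumption each marker mutated
exactly once, and a panel of representative chromosomes genotyped at many
markers determines where on the haplogroup tree each marker arose: its
*derived-sample set* must be exactly the set of chromosomes below one
branch.  `ytreemap` implements this mapping as a tested pipeline: parse a
marker catalog, hold three-valued genotype calls (derived / ancestral /
no-call), place markers on a backbone haplogroup tree, resolve polytomies
when repositioned markers group siblings, polarize sites with three alleles
using an outgroup, name the resulting haplogroups and paragroups, and
report the refinement as a diff against the backbone.

## The model and its assumptions

For directed binary characters (the ancestral state is known from an
outgroup), two markers are compatible on some rooted tree iff their derived
sets, restricted to jointly observed samples, are *nested or disjoint*.
This is the directed form of the four-gamete condition: the forbidden
pattern is a pair of overlapping, non-nested derived sets.  A whole matrix
admits a perfect phylogeny iff every marker pair is compatible, and the
minimal realizing tree is unique: its clades are exactly the distinct
derived sets (markers with identical sets are *phylogenetically
equivalent* and share a branch).  `build_perfect_phylogeny()` constructs
that tree directly from the laminar family of derived sets; the test suite
checks the theorem in both directions against an exhaustive enumeration of
rooted topologies on small leaf sets.

Placement (`place_markers_on_backbone()`) generalizes construction to a
partially known tree and incomplete typing.  Samples enter at the
haplogroup they were assigned to by prior genotyping (the panel was chosen
that way, so attachment is an input, not an inference) and each marker is
mapped by its observed derived set:

* equal to an existing branch's observed leaf set: the marker joins that
  branch (`existing_branch`), declaring equivalence with the markers
  already there.  This rule outranks the missing-data rule below, because
  identity of observed derived sets is positive evidence of co-location
  -- it is how a newly typed marker is recognized as equivalent to a
  known one rather than floated to the most rootward compatible position;
* a proper subset of one node's residue and/or children: a new node is
  created capturing exactly those samples and clades (`new_leaf_branch`,
  `split_branch`, or `root_of_clade` when two or more sibling clades are
  grouped -- the move that turns a trifurcation into two bifurcations);
* overlapping but non-nested with some clade: the marker is rejected as a
  candidate recurrent mutation (`unplaced_incompatible`) and can be routed
  to polarization;
* positions indistinguishable because of no-calls: the full candidate set
  is retained, the most rootward candidate is reported, and the placement
  is flagged putative.  No imputation is performed.

Marker classes are processed from largest derived set to smallest so that
rootward structure exists before tipward structure is hung below it; ties
are broken by marker name.  The procedure is idempotent, never removes a
backbone clade (refinement monotonicity), and every input marker ends on
exactly one branch or in the rejected set.

A branch is flagged *putative* (drawn dashed) when no sample below it has
a derived call at any marker on it -- the branching is then supported only
by absence or no-call patterns, with no positive control.

## Polarizing multiallelic sites

A site with three observed alleles (panel plus outgroup) cannot be one
UEP.  `polarize_multiallelic()` finds the minimum number of mutation
events explaining all raw calls by dynamic programming over node states
(unit cost per change) with the root fixed to the outgroup allele;
attached samples constrain the state of their node.  Events are named
`site.1`, `site.2`, ... in branch pre-order -- the drawing order of the
tree, recorded as a convention, since published `.1/.2` suffixes do not
state whether they follow discovery or tree order.  Ties among equally
parsimonious placements are broken toward the more rootward branch and
noted in the report.  The suite verifies minimality against exhaustive
state enumeration on small trees, and that replaying events down the tree
reproduces every raw call.  Without an outgroup call the events cannot be
rooted and polarization refuses to run.

## Nomenclature

Backbone names are never changed.  A new node receives a frozen
mutation-based name (clade letter, dash, lexicographically first marker on
its branch, e.g. `A-V218`), plus a lineage-based label extended from the
parent in sibling order where the parent's label is lineage-style (a
seventh branch under `C` becomes `C7`).  Lineage labels can cascade when
nodes are inserted, so they are reported side by side and the
mutation-based name is authoritative.  A node with children and attached
samples defines a paragroup, written with a trailing `*`.

`diff_trees()` matches nodes between backbone and refined tree by name or
by attached-sample clade and reports new haplogroups, new paragroups,
resolved polytomies (matched nodes whose out-degree strictly decreased),
repositioned markers and equivalence classes.  Two conventions matter for
the headline counts: paragroups are counted separately from haplogroups,
and a new node whose branch carries only repositioned backbone markers
(e.g. the node created when M112 moves up to group two former siblings)
is a polytomy resolution, not a new haplogroup.  The African filter is a
clade allow-list (letters `A` and `B`) applied to the samples below each
node, not sample-origin metadata: "African haplogroups" is a statement
about clades.

## The packaged fixture

The worked examples run on a fixture, built entirely in code
(`build_paper_fixture()`), that encodes the basal portion of the human MSY
tree and a 51-chromosome panel genotyped at 227 markers (22 newly
described, 146 previously reported, 59 backbone).  The published source
for this topology is a figure; its branch-by-branch marker lists for the
146 previously reported markers are not printed anywhere as a table, so
the fixture assigns synthetic V-numbers to those markers (the manifest
marks which names are real: the 22 new markers, V20, V45, V69, V88, V104,
V161, V186, V205, V218, V231, PK1 and the 59 backbone markers).  Every
quantitative statement the examples reproduce is encoded as data, not
asserted in code: the four basal-branch chromosomes share 19 of 32
candidate markers; the A1a panel of 23 markers splits into two branches
sharing all but four; V73 is equivalent to M114 and V249 to PK1; P289
moves above both A3a and A3b; five new haplogroups double the A3b1/A3b2
terminals; five new branches ladder the B2a clade; M112 resolves the
B2a/B2b/B2c trifurcation; seven markers shared by C, R and DE chromosomes
sit on the CT branch; V186/V205, V104 and V231 land at the roots of F, K
and P; and V161 polarizes into two events (A to C on the basal branch,
A to G at the root of its sister macro-haplogroup) given the outgroup
allele A.  The two collapsed substructures below B2b (2 and 8 internal
branches) are encoded as collapsed triangle nodes, excluded from counts.

Reconciling the per-clade itemization of new haplogroups with a total of
15 was a genuine design decision: the counting rules above give A1b 3
(two internal nodes plus the terminal defined by P114 and three other
mutations; the three paragroups are counted separately), A1a 1, A2 1,
A3 5 and B 5.  The alternative -- counting paragroups among the 15, or
counting the M112 node -- cannot be reconciled with the printed total
under any itemization we found, and is rejected by the conventions above.

## The simulator

`simulate_tree_and_markers()` draws a random rooted binary topology
(random sequential joins), assigns each branch a Poisson number of markers
(default mean 3, a realistic marker density for re-sequencing-derived
panels on a deep tree), and sets every marker's outgroup allele to its
ancestral state.  `genotype_panel()` types one-to-few representatives per
leaf -- emulating a representative panel design rather than
population-frequency sampling, because the analysis is placement, not
frequency estimation -- then injects recurrent or triallelic second events
at configurable rates and masks calls to no-call independently.  A second
event is always drawn on a sample-bearing lineage disjoint from the first:
an event on an ancestor would overwrite the first one's signal and an
event on an unsampled branch would be invisible, so neither emulates a
detectable second origin.  All draws
come from one seeded stream per function call, so a configuration
reproduces its data exactly.

What the simulator does *not* emulate: genotyping error (a wrong call, as
opposed to a missing one), linked microsatellite variation,
population-frequency structure, and sequence-level artifacts such as
paralogous misamplification.  Passing recovery tests therefore show that
the algorithms are correct under the stated model, not that real assay
error is handled; on real data, incompatible markers surface in the
`unplaced_incompatible` set for manual review rather than being silently
reconciled.

## Numerical and degenerate-input choices

* Derived sets and equivalence are computed over jointly observed samples
  only; a no-call never counts as derived.
* A marker with no derived call anywhere keeps its backbone branch: absence
  of evidence moves nothing.
* A marker derived in every sampled chromosome hangs on a trunk branch
  below the root (the root itself always stays all-ancestral).
* Deletions are single binary characters; multi-copy markers are single
  characters whose paralogous positions are metadata -- both are genotyped
  as one phylogenetic event.
* Reports sort markers and children lexicographically; sibling order in
  trees is file/creation order, which fixes event numbering.
* Polytomy resolution applies only when out-degree strictly decreases; no
  speculative groupings.

## Problem sizes used in the checks

The exhaustive-topology oracle enumerates all rooted multifurcating trees
for up to 6 leaves (2752 trees at n = 6, memoized); for 7-8 leaves the
independent check verifies laminarity and the minimal clade family
instead, which is equivalent for this property and keeps the suite quick.
Property tests run 500 random matrices up to 8 samples by 15 markers, 200
random polarization instances on trees of up to 6 leaves with 3 alleles,
and 100 seeded end-to-end recovery simulations on 6-leaf trees.  These
sizes were chosen as the smallest at which every combinatorial case
(polytomies, trunks, ladders, equivalence, rejection) occurs with high
probability.

## Known limitations

* Attachment of panel samples relies on their prior haplogroup assignment;
  a sample with a wrong prior is not re-derived from genotypes (its
  conflicting markers will instead show up as incompatible).
* Ambiguity reporting keeps the full candidate set but the tree stores a
  single (most rootward) position; alternative topologies are not
  enumerated.
* Lineage-based labels are best-effort outside strictly letter/number
  styled backbones; mutation-based names are always defined.
* No branch lengths, dating, or likelihood-based inference: the package
  maps UEP markers onto topologies, nothing more.
```
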