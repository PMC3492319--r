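# ytreemap

Phylogenetic mapping of Y-chromosome biallelic markers onto a backbone
haplogroup tree.

## The problem

The male-specific region of the Y chromosome (MSY) does not recombine:
its variants accumulate along a single genealogy, so each biallelic marker
(a unique-event polymorphism, UEP) defines a clade — a *haplogroup*.
Refining the deep, African-specific portion of the MSY tree means taking
markers discovered by re-sequencing a handful of chromosomes and
*placing* each one on the known tree from panel genotypes: the marker's
branch is the one whose descendants are exactly the chromosomes carrying
the derived allele.  `ytreemap` is for researchers doing exactly this
kind of marker mapping: it turns a marker catalog, a backbone tree, and a
sample × marker genotype matrix into a refined, named tree plus a
machine-readable report of what changed.

## The method

For directed characters (ancestral state fixed by an outgroup), two
markers are compatible on some rooted tree **iff** their derived-sample
sets are nested or disjoint (the directed four-gamete condition), and a
perfect phylogeny exists iff all pairs are compatible; its clades are
exactly the distinct derived sets.  On a partially known tree with
missing calls, each marker is mapped by its observed derived set *D*:

| observed pattern of *D* | placement |
|---|---|
| equals an existing branch's leaf set | joins that branch (phylogenetic equivalence, e.g. `V73 ≡ M114`) |
| proper subset of one clade's residue | new branch below it |
| union of ≥ 2 sibling clades | new internal node grouping them (resolves a polytomy) |
| overlaps a clade without nesting | rejected: candidate recurrent mutation |
| indistinguishable due to no-calls | most rootward candidate, flagged putative (dashed) |

Sites with three alleles are resolved into a minimum set of mutation
events by parsimony with the root fixed to the outgroup allele
(`V161 → V161.1, V161.2`).  New nodes get mutation-based names
(`A-V218`) and lineage labels (`C7`); paragroups carry a trailing `*`.

## Worked example

The package ships a fixture encoding the basal MSY tree and a
51-chromosome panel typed at 227 markers (22 newly described, 146
previously reported, 59 backbone):

```r
library(ytreemap)
fx  <- build_paper_fixture()
res <- refine_tree(fx$backbone, fx$gm, fx$catalog, fx$outgroup)
rep <- diff_trees(res$backbone_attached, res$tree,
                  region_filter = c("A", "B"), placements = res$placements)
rep
#> Refinement report (clades A, B)
#>   new haplogroups:     15 
#>     per clade:         A1a:1  A1b:3  A2:1  A3:5  B:5 
#>   new paragroups:      11 
#>   resolved polytomies: 1 
#>      B2 (3 -> 2) 
#>   repositioned markers: 58 
#>   equivalence classes (>1 marker): 41 
```

Reading the output: restricted to the African clades (A, B), placement
identifies 15 haplogroups absent from the backbone — 3 refining the basal
A1b branch, 1 splitting A1a, the new `A-V218` inside A-P262, 5 doubling
the A3b1/A3b2 terminals, and a ladder of 5 inside B2a — plus 11 new
paragroups (nodes whose residue chromosomes are derived at the node but
ancestral below it).  The B2a/B2b/B2c trifurcation collapses to a
bifurcation because M112's derived set turns out to cover B2b *and* B2c,
so it moves up to a new node grouping them; 58 markers in total sit on a
different branch than the coarse pre-study position (most are
re-sequencing-derived markers distributed from lumped branches into the
new substructure).  The triallelic site resolves as:

```r
res$events
#>   base_site event_name from to branch alternatives
#> 1      V161     V161.1    A  C    A1b             
#> 2      V161     V161.2    A  G  A1a-T             
```

i.e. two independent mutations from the outgroup allele A: A→C on the
A1b branch and A→G at the root of the sister macro-haplogroup.

A shell front end wraps the same functions:

```sh
exec/ytreemap fixture  --outdir fixture/
exec/ytreemap refine   --backbone fixture/backbone.nwk \
    --catalog fixture/catalog.tsv --matrix fixture/genotypes.tsv \
    --raw fixture/raw_alleles.tsv --outgroup fixture/outgroup.tsv \
    --region-filter A,B --outdir out/
exec/ytreemap simulate --leaves 12 --no-call-rate 0.1 --seed 7 --outdir sim/
```

## Package layout

* `R/catalog.R` — marker-table parsing (lenient + canonical TSV dialects)
* `R/genotype_matrix.R` — three-valued genotype container, derived sets
* `R/tree.R` — haplogroup trees, annotated-Newick I/O
* `R/phylogeny.R` — compatibility, perfect phylogeny, backbone placement
* `R/polarization.R` — outgroup-rooted minimal mutation events
* `R/nomenclature.R` — naming, tree diff, refinement report
* `R/simulate.R` — seeded panel simulator
* `R/fixture.R` — the packaged study fixture, built in code
* `vignettes/refining-the-basal-y-tree.Rmd` — model, assumptions, design
  decisions, limitations
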