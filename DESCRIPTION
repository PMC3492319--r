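Package: ytreemap
Title: Phylogenetic Mapping of Y-Chromosome Markers onto a Haplogroup Backbone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Places Y-chromosome biallelic markers onto a backbone haplogroup
    tree from panel genotypes under the unique-event-polymorphism (perfect
    phylogeny) assumption. Provides a marker catalog parser for tab-separated
    marker tables (including multi-copy and deletion variants), a three-valued
    genotype matrix container, directed character-compatibility tests and
    perfect-phylogeny construction, backbone placement with polytomy
    resolution and putative-branch flagging, outgroup polarization of
    triallelic sites into minimal mutation events, haplogroup/paragroup
    nomenclature, backbone-versus-refined tree diffs, and a seeded simulator
    of genotyping panels for validation. Ships a worked fixture encoding the
    basal (African) portion of the human MSY tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
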