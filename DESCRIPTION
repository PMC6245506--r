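Package: transrank
Title: Reference-Anchored Evaluation and Ranking of De Novo Transcriptome
    Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes fifteen evaluation parameters for de novo transcriptome
    assemblies (contiguity, gap, read-mapping, protein-annotation and
    ortholog-completeness statistics), projects assemblies and reference
    transcriptomes into a common standardized principal component space with
    the references treated as supplementary individuals, clusters assemblies
    by Ward hierarchical clustering on the retained components, and ranks
    assemblies by their mean Euclidean distance to the references (lower is
    better). Also enumerates the combinatorial graph of contig, scaffolding,
    concatenation, redundancy-removal, reconciliation and cross-platform
    merging strategies used to generate candidate assemblies, and provides a
    synthetic-data generator with controlled degradation (fragmentation,
    duplication, gap injection, chimerism) so the whole pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    ape,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
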