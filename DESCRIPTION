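Package: HexaMapQTL
Title: Integrated Linkage Mapping, Haplotype Reconstruction and Multi-Allelic
    QTL Analysis for Polysomic Hexaploids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing fully integrated and phased genetic
    linkage maps in polysomic polyploids (primarily hexaploids) from SNP
    dosage data of a bi-parental F1 population. Provides a generic
    maximum-likelihood engine for pairwise recombination-frequency, LOD and
    phase estimation under random bivalent pairing for all marker dosage
    types, homologue backbone clustering and chromosomal linkage-group
    assembly, allele-to-homologue phasing, weighted multidimensional-scaling
    marker ordering with principal-curve projection, identity-by-descent
    (IBD) haplotype-probability reconstruction on a centiMorgan grid with
    genotype information content, and multi-allelic QTL genome scans with
    permutation significance thresholds and per-allele effect estimates. A
    ploidy-general meiosis simulator with known truth supports validation
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, SNP, LinkageDisequilibrium, QualityControl, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'dosage-dist.R'
    'dosage-io.R'
    'filtering.R'
    'meiosis-sim.R'
    'linkage.R'
    'backbone.R'
    'ordering.R'
    'ibd.R'
    'qtl.R'
    'pipeline.R'
    'validation.R'
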