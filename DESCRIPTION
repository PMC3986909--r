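Package: ddRADmap
Title: Pseudo-Testcross Linkage Mapping, Scaffold Anchoring and Oxford-Grid
    Synteny for ddRAD Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational chain of a ddRAD-based genetic
    mapping and comparative genomics study in a diploid outbred cross:
    in-silico double-digest fragment recovery, genotype quality control and
    pseudo-testcross recoding, sex-specific linkage-map construction
    (two-point recombination/LOD, LOD grouping, SARF marker ordering,
    Kosambi distances, error-LOD genotype masking, Chakravarti map-length
    correction and genome-coverage estimation), anchoring and ordering of
    assembly scaffolds on the maps from similarity hit tables, and
    Oxford-grid synteny analysis with syntenic-box classification,
    ohnolog-quadruplet detection and parsimony-guided inference of
    post-whole-genome-duplication fusion/fission scenarios. A synthetic-data
    module generates genomes, backcross families, fragmented scaffolds and
    duplicated-then-rearranged two-species segment tables with known ground
    truth so every stage is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
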