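Package: plastomeDCAPS
Title: dCAPS Marker Design and Plastome Comparison for Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing cleaved amplified polymorphic sequence (CAPS)
    and derived CAPS (dCAPS) markers from near-identical chloroplast genomes.
    Detects specimen-specific substitutions and InDels from whole-plastome
    alignments, designs mismatch primers that complete a restriction site in
    exactly one allele, simulates PCR and restriction digestion to predict
    allele-specific band patterns, and genotypes cultivar panels. Supporting
    machinery covers quadripartite (LSC/IRb/SSC/IRa) partitioning of circular
    plastomes, junction-gene distance reports, pairwise identity/gap/SNP
    statistics, and deterministic synthetic-plastome generators for testing.
    Ships the trnL-UAA intron InDel assay for Hibiscus syriacus as a worked,
    fully offline example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    utils,
    stats,
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
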