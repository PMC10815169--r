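Package: DwTyper
Title: Marker-Assisted Genotyping and Cross Prediction for Sorghum Plant-Height Loci
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for molecular-marker-assisted dwarf breeding in grain
    sorghum (Sorghum bicolor). Calls alleles at the classical plant-height
    loci Dw1, Dw2 and Dw3 from PCR amplicon evidence (a diagnostic SNP, a
    2-bp deletion and an 882-bp tandem duplication, respectively), classifies
    inbred accessions into the Quinby-Karper dwarf classes, predicts F1
    genotypes for diallel and test-cross designs under independent Mendelian
    segregation, and summarises plant-architecture traits (plant height, stem
    height, spike stalk length, spike length, height under the flag leaf and
    the spike-stalk/stem-height ratio) per genotype class. Includes a
    synthetic-data generator producing allele-true amplicon sequences and
    genotype-class phenotype panels so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, Preprocessing
RoxygenNote: 7.3.3
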