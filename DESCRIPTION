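Package: alphoidr
Title: Alpha-Satellite Monomer Segmentation, Classification and
    Higher-Order Repeat Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of primate centromeric alpha-satellite
    DNA: orientation normalization and segmentation of tandem arrays into
    ~171-bp monomers, scanning of the 17-bp protein-recognition domains
    (pJ-alpha motif and CENP-B box), A/B-type classification by p-distance
    to type consensuses, higher-order repeat (HOR) periodicity detection,
    suprachromosomal family assignment, characterization of extra-long
    (~189-bp) insertion monomers, majority-rule consensus building over an
    extended ambiguity alphabet, and neighbor-joining phylogenetics with
    bootstrap support. Ships the gorilla alphoid consensus set and a
    ground-truth synthetic array simulator built from it.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
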