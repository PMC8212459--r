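Package: drebfam
Title: Genome-Wide Analysis of AP2/ERF (DREB) Transcription-Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for genome-wide characterisation of
    AP2/ERF-domain transcription-factor families, with an emphasis on the
    DREB (dehydration-responsive element binding) subfamily of autopolyploid
    plant genomes. Classifies proteins into superfamilies and DREB subgroups
    by domain architecture and conserved-motif diagnostics (WLG, V14/E19,
    NLS, DSAW, LWSY, CMIV-1), profiles physicochemical properties
    (ProtParam-style MW, pI, GRAVY, aliphatic and instability indices), maps
    tandem gene duplications by chromosomal windowing, estimates Ka/Ks by
    Nei-Gojobori (1986) counting with Jukes-Cantor correction and converts
    synonymous divergence to time, builds bootstrapped neighbor-joining
    trees from Poisson-corrected protein distances, and classifies FPKM
    expression patterns across tissues, leaf developmental gradients,
    diurnal cycles and abiotic-stress series. A synthetic-data generator
    produces fixtures with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
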