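Package: ms1screen
Title: Stepped Biomarker Screening by Targeted Label-Free MS1 Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tiered, gel-free biomarker screening pipeline for two-group
    bottom-up proteomics. Identification tables from a database search are
    filtered by peptide ion score, candidate proteins are triaged into a
    primary tier (group-exclusive identifications) and a secondary tier
    (shared identifications with a protein-score ratio of at least two), and
    candidates are then verified by targeted label-free MS1 quantification:
    extracted ion chromatograms at narrow ppm tolerance, scans-across-peak
    reliability gating, internal-standard normalization, cross-run retention
    time matching, and fold-change based certification with pseudo-ratio
    handling of peaks below the limit of quantification. A seeded synthetic
    LC-MS data generator (identification tables plus centroid MS1 mzML runs
    with known ground truth) makes every stage testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
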