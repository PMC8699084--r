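Package: secmapr
Title: SEC Co-Fractionation Antibody Microarray Processing and Multi-Omics
    Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes multiplex antibody microarray readouts of
    size-exclusion chromatography (SEC) fractions into background-corrected,
    MasterMix-corrected, biotin-normalized per-fraction protein signals;
    calibrates molecular weight against elution standards; calls protein
    assembly states (monomer, complexed, hydrolyzed) by comparing observed
    elution peaks with the theoretical molecular-weight fraction; and merges
    the resulting detections with label-free LC-MS/MS quantification and
    RNA-seq expression tables (overlap statistics, subcellular localization
    categories, LFQ/FPKM population groups). A forward simulator generates
    spot-level array data, elution profiles and omics tables with known
    ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
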