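Package: dualsip
Title: Dual Stable-Isotope-Probing Analysis of DNA, Lipid and Metabolite Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting stable-isotope-probing (SIP) incubations that
    combine 13C and deuterium labels. Covers the three layers such experiments
    produce: DNA-SIP density-gradient fraction tables, analysed with per-taxon
    ratio-of-odds-ratios (RoOR) statistics, replicate consensus and read filters;
    compound-specific PLFA isotope measurements, converted to label-incorporation
    rates and an Ra/Rt heterotroph/autotroph discriminant; and high-resolution
    mass-spectrometry peak lists, searched for 13C and deuterium isotopologue
    series including the divisible-by-three CD3 methyl-transfer signature.
    Includes synthetic-data generators with known ground truth for all three
    layers and a pipeline runner with provenance tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
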