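Package: xlms
Title: MS2-Only Search Engine for MS-Cleavable Cross-Linking Mass Spectrometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cross-linked peptide pairs from centroided MS2 spectra
    acquired with MS-cleavable cross-linkers such as DSSO and DSBU. Stump-ion
    doublets (light/heavy linker fragments separated by a linker-specific mass
    difference) are detected to infer the neutral masses of the two linked
    peptides, each peptide is identified independently with a binomial
    probability score weighted by explained intensity, candidate pairs are
    constrained by the precursor mass relation and combined into cross-link
    spectrum matches, and results are validated by target-decoy false
    discovery rate estimation at both the spectrum-match and the cross-link
    level, optionally with intra/inter-protein separation. Includes in-silico
    tryptic digestion, reversed-decoy generation, a mass-searchable candidate
    index, MGF/mzML readers, a synthetic cross-link spectrum generator for
    end-to-end testing, and an xiView-compatible cross-link exporter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Biostrings
Suggests:
    mzR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
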