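Package: proteoMSI
Title: Proteoform and Metabolite Annotation for Ultra-High-Resolution
    MALDI Mass Spectrometry Imaging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation and quantification toolkit for isotopically
    resolved MALDI-FTICR mass spectrometry imaging of intact proteins and
    metabolites.  Computes exact isotope envelopes for proteoforms
    (sequence variants, PTM stacks, adducts, charge states 1-3), matches
    them against region-restricted bottom-up identification lists by
    accurate mass and envelope correlation, corroborates assignments
    across charge states, compares MSI fold changes with label-free
    peptide-area quantification, and assigns elemental formulas to
    metabolite peaks by accurate mass and isotope pattern.  Includes a
    seeded FTICR-like spectrum and dataset simulator (imzML output) for
    ground-truth validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'isotope-data.R'
    'ElementalComposition.R'
    'IsotopeEnvelope.R'
    'modifications.R'
    'sequence.R'
    'proteoform.R'
    'imzml.R'
    'roi.R'
    'spectra.R'
    'matcher.R'
    'quant.R'
    'metabolite.R'
    'simulate.R'
    'pipeline.R'
    'benchmark.R'
    'proteoMSI-package.R'
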