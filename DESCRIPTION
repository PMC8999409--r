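Package: GlycoSda
Title: Identification and Relative Quantification of Sda-Epitope Glycopeptides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mass-spectrometric glycoproteomics of the Sda
    (Sd(a)/Cad) blood-group epitope, a GalNAc-beta1,4-(NeuAc-alpha2,3-)Gal
    determinant that appears at the composition level as one extra HexNAc on
    a sialylated galactose. The package provides monoisotopic mass arithmetic
    for peptides, modifications and glycan compositions; in-silico protease
    digestion (trypsin, chymotrypsin, pronase) with reversed-sequence decoys;
    tiered-collision-energy HCD fragment prediction (glycosidic Y-ion
    ladders, oxonium B-ions, backbone b/y ions); glycopeptide-spectrum
    matching with composition-aware verification rules and target-decoy FDR;
    a run-wide MS2 diagnostic-ion chromatogram for the Sda oxonium ion at
    m/z 860.3143; MS1 extracted-ion-chromatogram quantification of Sda
    glycoforms relative to their precursor glycoforms; and a seeded
    ground-truth run simulator emulating stepped-NCE Orbitrap acquisition
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'GlycoSda-package.R'
    'diagnosticScreen.R'
    'digestion.R'
    'fragmentation.R'
    'glycanLibrary.R'
    'io.R'
    'massCore.R'
    'matching.R'
    'pipeline.R'
    'quant.R'
    'simulate.R'
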