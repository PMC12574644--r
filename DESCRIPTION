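Package: phageDesign
Title: Programmable M13 Phage ssDNA Design and Antigen Display Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational toolkit for programmable M13 bacteriophage
    nanovaccines. Designs single-stranded DNA genome inserts with a
    controlled CpG (CG dimer) fraction, converts a chosen fraction of CG
    dimers into canonical immunostimulatory CpG hexamers (AACGTT/GACGTT),
    and eliminates direct repeats and hairpin-forming inverted repeats by
    iterative A/T transversion. Quantifies the antigen pVIII display ratio
    of mosaic phage capsids by double-Gaussian deconvolution of HPLC
    chromatograms, including a synthetic-chromatogram simulator for
    estimator validation. Also predicts MALDI-TOF [M+H]+ peaks for capsid
    proteins and maps ssDNA length to expected phage filament length.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
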