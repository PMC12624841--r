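Package: Jdeconv
Title: Conformer Population Deconvolution from Scalar J-Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for NMR-based conformational analysis of pyranose
    glycosylamines and related small molecules. Predicts conformer-pure
    vicinal couplings from dihedral angles with basic and generalized
    (Haasnoot-Altona type) Karplus equations and idealized pyranose chair
    templates, deconvolves ensemble-averaged experimental couplings into
    conformer populations on the probability simplex (two-state 4C1/1C4
    ring fits and multi-conformer aglycone rotamer fits under a mean
    absolute error objective), converts conformer free energies into
    Boltzmann populations and Boltzmann-averaged properties, and fits
    first-order approach-to-equilibrium kinetics to reaction time series.
    Includes a synthetic-data generator emulating the statistical
    structure of ensemble-averaged coupling measurements so every stage
    of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'boltzmann.R'
    'karplus.R'
    'chair.R'
    'coupling_io.R'
    'data_access.R'
    'ensemble_fit.R'
    'kinetics.R'
    'ring_fit.R'
    'simulate.R'
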