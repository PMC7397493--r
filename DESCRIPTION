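Package: microshred
Title: Fragment-Based Phasing and Data Reduction for Microcrystal
    Electron Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phasing microcrystal electron diffraction (MicroED)
    data with polyalanine fragment libraries derived from distant homologues.
    Implements sequential ("shred") and spherical fragment generation with a
    per-residue Shred-LLG descriptor, rotation and translation searches
    against normalized intensities using electron scattering form factors,
    rigid-body refinement and likelihood-style placement scores, phase-error
    and map-based solution diagnostics (weighted mean phase error, amplitude
    correlation, omit-map peaks), and MicroED data-reduction heuristics:
    per-crystal scaling, CC1/2-driven omission of radiation-damaged frames,
    and minimal-crystal merge-set selection.  A synthetic-data module
    simulates multi-crystal MicroED experiments (wedge incompleteness,
    missing cone, per-frame damage, per-crystal scale and B differences)
    from built-in ground-truth folds so the whole workflow runs end to end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'diffraction.R'
    'formfactors.R'
    'fragmentation.R'
    'geometry.R'
    'merging.R'
    'microshred-package.R'
    'model-io.R'
    'peptide.R'
    'phasing-metrics.R'
    'pipeline.R'
    'search.R'
    'spacegroups.R'
    'synthetic-data.R'
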