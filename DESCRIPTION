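Package: panRTA
Title: Pan-Allotype Thermodynamic-Average Prediction of Peptide Binding
    to Class II MHC
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts peptide binding affinities for class II MHC
    allotypes, including allotypes without experimental binding data, by
    Boltzmann-averaging over all 9-mer binding registers of a peptide.
    Per-register energies are sums of contributions from peptide core
    residues contacting groups of co-occurring polymorphic MHC residues,
    so a single parameter set transfers across allotypes encoded by their
    residue-variant-group membership. Parameters are fitted by
    L1-constrained mean-square-error minimization with multistart
    projected-gradient solves and an SVD-based initializer combining
    single-allotype models. Includes residue-variant-group construction
    from structures and aligned sequence panels, allotype coverage
    profiling, leave-one-allele-out cross-validation, exact Wilcoxon
    signed-rank comparison, per-position binding-specificity variation,
    binding-core identification, and a synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
biocViews: Software, Proteomics, ImmunoOncology, SequenceMatching
RoxygenNote: 7.3.3
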