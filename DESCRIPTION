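Package: glycolattice
Title: Glycoform Lattice Analysis of Native Mass Spectra of Membrane
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intact-mass analysis of heavily glycosylated membrane protein
    complexes measured by native mass spectrometry. Implements exact mass
    arithmetic for monosaccharide residues and adducts, combinatorial
    glycoform ladders and their repeat-unit statistics, charge-state
    inference and lattice-constrained zero-charge deconvolution,
    proteoform annotation (N-glycan branch and antennary-fucose series,
    phospho/palmitoyl/phospholipid adducts), differential desialylation
    and subunit-dissociation comparisons, binomial oligomer-assembly
    models, and mass-photometry mixture quantification, together with a
    synthetic-data engine that emulates electrospray spectra of a
    glycoprotein heterodimer and its super-dimer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mzR
Config/testthat/edition: 3
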