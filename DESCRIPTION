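Package: fretpda
Title: Single-Molecule FRET Burst Analysis and Probability Distribution
    Analysis for Membrane-Protein Hairpin Folding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the conformational equilibrium of
    transmembrane helical hairpins from diffusion-based single-molecule
    FRET measurements with pulsed-interleaved excitation (PIE/ALEX).
    Provides a seeded photon-stream simulator of freely diffusing
    dual-labeled two-state molecules, all-photon sliding-window burst
    selection, ALEX-2CDE/FRET-2CDE kernel-density and burst-asymmetry
    filtering, stoichiometry-based species sorting, shot-noise-limited
    probability distribution analysis (PDA) of FRET efficiency histograms
    to recover state fractions and inter-dye distances, two-state folding
    free energies, four-parameter logistic dose-response fitting of
    corrector rescue (EC50), and sequence-based membrane-insertion
    energetics (Wimley-White transfer free energies, hydrophobic moment,
    Liu-Deber segmental hydrophobicity).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
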