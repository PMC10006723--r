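Package: peptaifold
Title: Peptaibol Sequence Analysis and Folding-Dynamics Landscapes from
    Accelerated Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for structure-activity analysis of peptaibols, fungal
    peptides rich in non-standard residues (Aib, C-terminal amino alcohols).
    Handles three-letter-code sequences with acetylated N-termini, computes
    nominal b/y fragment-ion masses for the labile Aib-Pro cleavage,
    classifies sequences by the R11-R14 motif, and aggregates strain
    production profiles. The folding-dynamics chain reads per-frame backbone
    dihedral tables, performs dihedral-angle principal component analysis
    (dPCA) on sin/cos features, reweights accelerated-MD boost potentials
    (exponential or Maclaurin series), builds free-energy landscapes
    mu = -kT ln P over principal-component densities, and identifies
    conformational clusters as density peaks with per-frame assignment,
    occupancy accounting and representative frames. A seeded synthetic
    generator of Markov-switching metastable dihedral trajectories with a
    state-dependent boost series provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
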