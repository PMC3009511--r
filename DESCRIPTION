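Package: fccfold
Title: Hybrid Constraint-Programming and Simulated-Annealing Protein Folding
    on the Face-Centered-Cubic Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice protein structure prediction on the face-centered-cubic
    (FCC) lattice with a 20-amino-acid pairwise contact-potential energy
    function. A finite-domain constraint solver over box domains exhaustively
    enumerates re-placements of short subchains and serves as the
    large-neighbourhood generator for a logarithmic-cooling simulated
    annealing search. Includes a pure constraint-programming branch-and-bound
    mode, FCC geometry utilities (adjacency, bond angles, self-avoiding-walk
    counting), contact-energy evaluation, plain-text conformation and
    potential-table formats, a PDB C-alpha trace writer, and seeded fixture
    generators for sequences and toy potential tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    bio3d,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
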