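Package: scc2
Title: Similarity-Constrained CC2 Electronic Structure with Correct
    Conical Intersections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Second-order approximate coupled cluster (CC2) ground and
    equation-of-motion excited states, together with the similarity-
    constrained CC2 (SCC2) model that restores correct conical-intersection
    topology between same-symmetry excited states: real excitation energies,
    point degeneracy and linear lifting in the branching plane, where
    standard CC2 produces complex-energy intersection tubes.  Includes a
    self-contained reference layer (Gaussian AO integrals over contracted
    s/p shells, restricted Hartree-Fock, MO transformation), a DIIS
    amplitude solver with folded doubles, dense and Davidson non-symmetric
    eigensolvers, a full-configuration determinant-space oracle for
    validating every working equation on small systems, and surface-scan
    tooling for locating intersections and quantifying their topology.
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
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
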