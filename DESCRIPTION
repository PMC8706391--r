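Package: fragrecon
Title: Fragment-Based Deconstruction-Reconstruction Design of Hsp90 Inhibitor Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a fragment-based drug-design pipeline for generating
    candidate Hsp90 inhibitors from a library of known ligands.  Known ligands
    are deconstructed into rule-of-three compliant sub-ligands carrying
    attachment markers, deduplicated by fingerprint Tanimoto similarity, and
    recombined either semi-exhaustively (every header crossed with every body,
    residual attachment points filled at random, Lipinski/Veber filtering, and
    full census accounting) or by a simulated-annealing search over
    header-plus-bodies assemblies with change and swap moves.  Scoring is
    pluggable: a lookup scorer over the packaged reference library of 68 Hsp90
    ligands with docking-derived binding energies, a deterministic descriptor
    surrogate for testing, and an adapter contract for external docking
    engines.  Chemistry (SMILES canonicalization, descriptors, fingerprints)
    is delegated to OpenBabel through ChemmineOB/ChemmineR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
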