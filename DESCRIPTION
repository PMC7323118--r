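Package: echbend
Title: Energy Convex Hull Model of Strong Polymer Bending and DNA Cyclization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strong bending of semiflexible polymers, in
    particular double-stranded DNA, with the energy convex hull (ECH) model.
    Represents per-site effective bending-energy profiles (empirical quartic,
    harmonic worm-like chain, or tabulated), detects their non-convex region by
    a double-tangent (convex hull) construction, and derives the piecewise
    harmonic/linear bending energy, closed-loop energies and Shimada-Yamakawa
    cyclization j-factors with optional torsional modulation, including the
    predicted j-factor minimum for very short loops. Includes coarse-grained
    Metropolis Monte Carlo samplers and a FIRE energy minimizer (one bead per
    base pair) for closed DNA loops and for an open charged chain confined by
    an attractive impenetrable core, used to test the hull-following behaviour
    of strongly bent chains.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
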