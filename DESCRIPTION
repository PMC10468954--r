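Package: fluxcone
Title: Exact Geometry of the Steady-State Flux Cone and Elementary Flux Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact rational construction and analysis of the steady-state flux
    cone of a metabolic network. Provides elementary flux mode (EFM)
    enumeration by reversible-reaction splitting and the double description
    method, an independent brute-force enumerator based on the rank test,
    the degree of a flux vector (the dimension of its minimal containing
    face), minimal metabolic behaviors and their one-to-one correspondence
    with minimal proper faces, face-lattice enumeration for small cones,
    detection of blocked reactions and redundant irreversibility
    constraints with lexicographic canonicalization, flux balance analysis
    by exact rational simplex, and constructive decomposition of flux
    vectors into few low-degree EFMs via Caratheodory reduction. All
    geometric decisions (ranks, dimensions, supports, memberships) are made
    in exact rational arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
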