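Package: polyfluid
Title: Configurations of Small Polyelectrolytes in Crowded Biological Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the size and shape of short polyelectrolytes (such as
    single-stranded DNA oligomers) in crowded fluids. Implements the
    salt-dependent scaling law for the radius of gyration, a generalized
    Lennard-Jones effective potential encoding the competition between
    short-range electrostatic stretching and long-range entropic compression,
    coordinate-level generators for idealized chain configurations (straight
    rope, ring, parabola, dense and sparse spheres, self-avoiding walk), the
    wormlike-chain radius of gyration, and conversions among the radius of
    gyration, hydrodynamic radius and end-to-end distance. Reference grids of
    all derived quantities can be regenerated as CSV and checked against
    bundled printed-value fixtures with a known-discrepancy ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
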