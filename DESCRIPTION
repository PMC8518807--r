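Package: nessflow
Title: Mass-Action Reaction Networks with Non-Equilibrium Entropy Accounting
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic simulation of mass-action chemical reaction
    networks in closed and open-flow (CSTR) systems, with complete
    non-equilibrium thermodynamic bookkeeping: per-reaction affinities,
    internal and exchange entropy production and their balance at
    non-equilibrium stationary states (NESS), the Glansdorff-Prigogine
    general evolution criterion, Jacobian/Routh-Hurwitz stability
    classification, parameter-branch scans with hysteresis detection, and
    local-potential probing of stationary states.  Ships presets for a
    competitive-selectivity CSTR, the Schloegl bistable model and the Frank
    model of spontaneous mirror symmetry breaking, plus a seeded generator
    of thermodynamically consistent random networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    MASS,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
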