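Package: spinalcpg
Type: Package
Title: Conductance-Based Models of the Spinal Locomotor Central Pattern Generator
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulation and analysis of bilateral spinal locomotor central
    pattern generator (CPG) circuits built from genetically identified
    interneuron classes (V0D, V0V, V1, V2a, V2b, V3). Provides
    Hodgkin-Huxley style neuron populations whose rhythmogenesis rests on a
    slowly inactivating persistent sodium current, declarative builders for
    two commissural-pathway architectures and a unified V1/V2b architecture,
    in-silico lesion, hemisection and axon-guidance knockout transforms,
    piecewise-linear excitability (drive) protocols, a fast compiled network
    simulator with seeded reproducibility, and analysis routines for rhythm
    frequency and amplitude, left-right and flexor-extensor coordination via
    circular statistics, burst-deletion classification, and phase-duration
    asymmetry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
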