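Package: wavenav
Title: Parallel Path Planning with Spiking Wavefronts and Anti-STDP in a Place-Cell Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hippocampus-inspired network of place cells in which a
    single propagating wavefront of spikes, combined with reverse (anti-)
    spike-timing-dependent plasticity, writes a synaptic vector field into the
    recurrent connectivity. The field converges on the wavefront's seeding
    target(s) and steers a simulated agent along near-shortest paths, including
    competition between multiple targets with unequal rewards and storage of
    several environments in one network. Provides maze geometries with
    polygon containment and specular reflection, an exploration phase that
    learns local excitatory connectivity from co-activation statistics,
    an adaptive leaky integrate-and-fire core with supralinear synaptic
    summation and continuous global inhibition, gated sign-switchable STDP,
    graph-geodesic oracles, and spike-force agent navigation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
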