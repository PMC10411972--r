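Package: msngain
Title: Biophysical Modelling of Excitation/Inhibition Integration in Striatal Medium Spiny Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how synaptic excitation and inhibition shape the
    firing output of striatal D1 medium spiny neurons (D1-MSNs). The package
    reads, writes, synthesizes and quantifies SWC dendritic morphologies
    (Sholl profiles, branch metrics, neuropil coverage), builds multicompartment
    conductance-based cable models with AMPA/NMDA/GABA-A synapses, calibrates
    synaptic conductances against miniature postsynaptic current amplitude and
    kinetics, drives the calibrated cell with randomized excitatory and
    inhibitory input ensembles over a frequency grid to obtain firing-rate
    surfaces, iso-firing contours and gain/offset decompositions, and computes
    the transporter-blockade arithmetic that attributes GABA supply to neuronal
    glutamate uptake, glial uptake and de novo synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
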