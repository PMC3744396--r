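Package: vasomodel
Title: Spiking and Stimulus-Secretion Coupling in Vasopressin Neurons
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulator for hormone secretion from hypothalamic vasopressin
    (magnocellular) neurons. Couples a modified integrate-and-fire spiking
    model that reproduces phasic (burst-and-silence) firing under Poisson
    synaptic bombardment to a single-compartment model of stimulus-secretion
    coupling with spike broadening, calcium-dependent facilitation and
    fatigue, and a depletable two-pool vesicle store. Includes stimulation
    protocol generators, spike-train and time-series analysis tools
    (burst detection, activity quotient, secretion per spike), heterogeneous
    population simulation with lognormal synaptic input densities, and
    config-driven experiment drivers with CSV output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
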