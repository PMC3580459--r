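Package: adwm
Title: Quantitative Systems Pharmacology of Working Memory in Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A two-part quantitative systems pharmacology platform linking receptor-level
    drug action to a cognitive readout in Alzheimer's disease. A receptor-competition
    model simulates neurotransmitter, drug, metabolite and radiotracer binding at
    cholinergic and serotonergic synapses with autoreceptor-regulated quantal release;
    a conductance-based prefrontal-cortex network of multicompartment pyramidal cells
    and interneurons produces a working-memory span. Clinical dose chains (AChE
    inhibition, 5-HT6 antagonism, memantine), disease pathology (synapse and neuron
    loss, cholinergic deficit, ApoE4 genotype) and design-of-experiments calibration
    against ADAS-Cog trial outcomes connect the two.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp (>= 1.0.0), stats, utils, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
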