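Package: follisim
Title: Compartmental Cyclic-Nucleotide Dynamics and Ratiometric FRET
    Imaging of Preovulatory Follicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic three-compartment model of luteinizing-hormone
    (LH) induced cAMP and cGMP dynamics in mouse preovulatory follicles
    (outer mural granulosa, cumulus, oocyte), coupled by gap junctions with
    a transient connexin-43 permeability dip and competitive inhibition of
    the oocyte phosphodiesterase PDE3A by cGMP.  Includes Hill-type
    calibration between cyclic-nucleotide concentration and the CFP/YFP
    emission ratio of the cAMPFIRE-M and cGi500 FRET sensors, a synthetic
    two-channel 16-bit time-lapse generator with ground truth, and the
    matching image-analysis pipeline (registration, region-of-interest
    traces, background and spectral-overlap correction, kinetic landmark
    metrics, nuclear-envelope-breakdown detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
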