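Package: stimstab
Title: Stability and Calcium-Signalling Analysis of S-Nitrosylated STIM Luminal Domains
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of S-nitrosylation effects on the STIM2
    luminal domain and downstream store-operated calcium entry. Provides
    Boltzmann sigmoid fitting of circular-dichroism thermal melts with
    apparent-Tm extraction, global two-state linear-extrapolation fitting of
    replicate urea denaturation curves (shared Gibbs free energy and m-value,
    per-replicate baselines) with quadrature error propagation for
    stability differences, weighted 1H-15N chemical-shift-perturbation
    profiling with sequence-cluster detection and PDB B-factor mapping, and
    Fura-2 ratiometric calcium trace processing with Grynkiewicz
    calibration. Synthetic-data generators with known ground truth exercise
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
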