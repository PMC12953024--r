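Package: ventbars
Title: Beta-Adrenergic Stimulation in Human Ventricular Myocytes and Tissue
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-population extension of the Ten Tusscher-Panfilov (2006)
    human ventricular ionic model in which nine PKA targets (INa, ICaL, IKs,
    IpK, INaK, RyR release, SERCA uptake, subspace-to-cytosol Ca2+ transfer
    and cytosolic Ca2+ buffering) each carry a phosphorylated and a
    non-phosphorylated channel population mixed by an isoproterenol
    dose-response fraction. Provides single-cell pacing, voltage-clamp and
    restitution protocols, an explicit monodomain reaction-diffusion solver
    for 1-D cables and 2-D sheets with heterogeneous adrenergic-stimulation
    maps, S1-S2 rotor induction, and a Hilbert-phase rotor analysis pipeline
    (phase-singularity detection, tracking, angular speed, localization area,
    wavelet counting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
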