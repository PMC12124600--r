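Package: gnrhephys
Title: In Vivo Electrophysiology of GnRH Neurons: Simulation, Sorting,
    Identification and Estrous-Cycle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing in vivo extracellular recordings of
    gonadotropin-releasing hormone (GnRH) neurons in freely moving mice.
    Provides an inhomogeneous-Poisson simulator of chemogenetically
    perturbable spike trains with ground-truth labels, spike detection and
    PCA-based sorting of raw voltage traces, the dual kisspeptin/CNO
    excitatory-rate criteria that identify GnRH neurons in hM4D(Gi) and
    hM3D(Gq) mouse models, estrous-stage firing-rate profiling, 20-hour
    surge-like versus basal-rhythmic subtype classification, biphasic
    waveform duration features, and the associated statistics (one-way
    ANOVA with Tukey HSD, Holm-Sidak step-down adjustment, per-timepoint
    repeated-measures contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
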