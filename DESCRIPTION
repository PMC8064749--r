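Package: pruriphys
Title: Pruriceptive Nociceptor Spike Trains, Itch Psychophysics, and DRG
    Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of primate pruriception
    experiments. Classifies polymodal C-fiber (CMH) heat responses into
    quickly and slowly adapting subtypes (QC/SC) from smoothed instantaneous
    discharge frequency, scores pruritogen-evoked spike-train responses
    against vehicle and spontaneous baseline (net action potentials,
    responsiveness, binned time courses), computes generalized Labeled
    Magnitude Scale (gLMS) rating metrics (peak, duration, area under the
    curve) with repeated-measures ANOVA using the Greenhouse-Geisser
    correction, and quantifies RNAscope puncta co-expression in dorsal root
    ganglion neurons. A synthetic-data module generates every input with
    declared ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
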