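Package: circalarva
Title: Circadian Behavior and Cellular Clock Phase Analysis for Larval
    Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bout-based rest/activity quantification of larval zebrafish
    locomotor tracks at 1-second resolution, chi-square periodogram
    detection of circadian rhythmicity in binned activity, cosinor
    analysis (mesor, amplitude, acrophase) of bioluminescence and gene
    expression time courses, and circular statistics (Rayleigh test,
    resultant length) for single-cell clock phase synchronization.
    Includes an alternating-renewal simulator of larval locomotor tracks
    with genotype presets, damped single-cell oscillator traces, and
    light-inducible expression courses, so every analysis stage can be
    exercised end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
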