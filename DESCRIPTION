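Package: equiconn
Title: EEG Connectivity Analysis of the First Night Effect in Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band-wise functional connectivity analysis for multichannel
    full-band DC EEG recordings from an eight-electrode equine montage, as
    used to detect the First Night Effect (compromised sleep in an unfamiliar
    stabling environment). Implements zero-phase third-order Butterworth band
    decomposition (delta through gamma), rank-biserial correlation maps over
    all 28 electrode pairs with bootstrap confidence intervals, Welch
    magnitude-squared coherence including a delta-versus-raw cross-frequency
    variant, zero-lag cross-correlation counts grouped into interhemispheric
    (H1-H4) and intrahemispheric (V1-V3) electrode groups with Wilcoxon
    rank-sum contrasts, reading and writing of recordings as EDF or plain
    numeric matrices with structured sidecars, and a synthetic cohort
    generator with controlled cross-channel coupling so that every pipeline
    stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
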