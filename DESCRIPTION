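Package: sedbench
Title: Surface Fine Sediment Benchmarks and Macroinvertebrate Response
    Assessment for Wadable Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and applies stream surface fine sediment (sand and
    fines, SF) benchmarks and macroinvertebrate Fine Sediment Biotic Index
    (FSBI) benchmarks for wadable (1st-4th Strahler order) streams. Computes
    percent surface fines from Wolman pebble counts, scores FSBI from taxa
    occurrence, fits 75th-percentile quantile regressions of SF on bankfull
    width to obtain reach-specific reference benchmarks, fits per site-class
    and stream-order logistic stressor-response models and inverts them to
    SF values with 50% and 75% probability that FSBI is worse than
    reference (SR50/SR75), estimates design-weighted relative risk of poor
    biological condition given benchmark exceedance, and rates each sample
    event's strength of evidence for a sediment-induced macroinvertebrate
    community composition change (unlikely / mixed evidence / likely). A
    synthetic-data generator emulating BURP-style monitoring datasets with
    known truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
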