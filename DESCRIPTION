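Package: afmonitor
Title: Atrial Fibrillation Detection from Inter-Beat Intervals via Lorenz Plot Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects atrial fibrillation (AF) episodes from 2-minute windows
    of inter-beat (RR) intervals using the Lorenz scatter-plot algorithm: the
    successive differences of RR intervals are binned into a 31x31 histogram,
    summarised over a 13-region segmentation of the plot domain, and reduced
    to an integer AFEvidence statistic compared against a fixed threshold.
    Includes a software emulation of a wearable single-lead ECG front end
    (band-pass conditioning and Pan-Tompkins R-peak detection), a seeded
    synthetic rhythm generator (normal sinus rhythm, AF, premature atrial
    contractions, and synthetic ECG), readers and writers for WFDB records,
    rhythm annotations and the 2-byte-per-interval device packet format, and
    a windowed evaluation harness reporting accuracy, sensitivity and
    specificity per record and pooled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
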