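Package: nervequant
Title: Quantification of Peripheral Nerve Activity Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify multi-unit peripheral nerve activity from
    multichannel electrophysiology recordings: band-pass and mains-notch
    filtering, rectified leaky integration, noise-floor-referenced spike
    detection, burst-ensemble counting, vagus nerve stimulation protocol
    scheduling, per-bin firing and amplitude summaries, group statistics
    (pooled t test, two-way cell-means ANOVA with Tukey-Kramer post hoc),
    and intermodes histogram thresholding for stained-area quantification.
    Includes a ground-truthed synthetic-recording and synthetic-image
    generator so every stage of the pipeline can be validated without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
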