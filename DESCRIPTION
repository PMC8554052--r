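Package: flyfae
Title: Food-Approaching Event Detection and Feeding-Rhythm Analysis for
    Drosophila Tube Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying feeding rhythms of individually housed
    Drosophila from one-frame-per-second position traces recorded in glass
    tube activity monitors. Segments each trace into food-approaching
    events (FAE) using a per-day food-surface estimate and a one-body-length
    feeding zone, calibrates a duration band filter (default 7-300 s)
    against manually annotated feeding and no-feeding visits, and summarises
    the retained events into hourly and windowed circadian indices: event
    counts (FAEn), residence time (FAErt) and residence time per event
    (FAErt/n). Includes a minimal centroid tracker for grayscale frame
    stacks, a synthetic-behavior simulator with programmable circadian visit
    rates for validation, group aggregation with standard comparisons, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
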