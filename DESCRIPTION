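Package: neoalarm
Title: Alarm-Burden Analysis for Neonatal Pulse-Oximetry Traces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pulse-oximetry alarm burden in newborn
    units from 0.5 Hz monitor trace exports: trace ingestion in a documented
    CSV dialect, data-integrity filtering (invalid readings, low signal
    quality, sensor-off and low-perfusion segments), segmentation of per-cell
    alarm annotations into discrete alarm events under a 30-second gap rule,
    per-neonate and cohort burden statistics (alarm densities, duration
    distributions, out-of-range fractions), a re-implementation of the
    monitor's alarm generation (trailing averaging, threshold check, alarm
    delay, rapid-desaturation override) for what-if sweeps over alternative
    thresholds and delays, and a calibrated synthetic neonatal vitals
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
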