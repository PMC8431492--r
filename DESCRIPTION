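Package: skelquant
Title: Movement Quantification from 2D Pose Keypoint Time Series
Version: 0.1.0
Authors@R:
    person("Skelquant", "Developers", email = "skelquant@example.org",
           role = c("aut", "cre"))
Description: Quantifies body movement from 2D pose keypoint sequences in the
    OpenPose BODY_25 dialect (or a flat CSV). From each recording it computes
    eleven per-frame skeleton parameters (shoulder, hip and thigh angles and
    lengths, and the trunk angle), summarises each parameter series with its
    lag-1 autocorrelation, the lag-1 autocorrelation of the differenced
    series, and a non-overlapping-window averaged variance (33 features per
    recording), and compares paired before/after cohorts with two-tailed
    paired t-tests. Includes a seeded synthetic seated-motion simulator
    (AR(1) joint jitter plus sway and swivel oscillations) so the whole
    pipeline is testable without patient videos, and a command-line
    interface (exec/skelquant).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
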