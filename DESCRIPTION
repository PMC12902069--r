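Package: dyadsync
Title: Dyadic Eye-Tracking Synchronization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual eye-tracking studies of interpersonal
    coordination. Implements pupillometry artifact rejection (blink and saccade
    interpolation, dilation-speed MAD filtering, gap-edge trimming, sparsity
    filtering, missing-data exclusion), pupil dilation velocity peak detection
    (Savitzky-Golay smoothing, derivative thresholding, non-maximal
    suppression), per-phase fixation and blink metrics, windowed nearest-event
    synchronization statistics for blink onsets and dilation peaks, and linear
    mixed-effects inference with variance decomposition (marginal and
    conditional R squared). Includes a synthetic dyad generator with known
    ground truth (coupled blink point processes, event-related pupil traces,
    injected sensor artifacts) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
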