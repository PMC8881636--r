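Package: erpcase
Title: Single-Subject Bootstrap Analysis of ERP Emotional Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-by-case statistical analysis of event-related potential
    (ERP) emotional-modulation effects. Provides a synthetic epoched-EEG
    generator with spatially correlated 1/f noise and injected early
    posterior negativity (EPN) and late positive potential (LPP) effects,
    a preprocessing chain (Butterworth band limiting, baseline adjustment,
    average reference, trial-count equating), cluster-mean component
    scoring with fixed or individually adapted time windows, single-subject
    bootstrap significance tests with graded p-value criteria, bootstrap
    signal-to-noise-ratio confidence intervals, mirrored-stimulus
    specificity (false-alarm) analysis, and group-level statistics
    (paired t / Cohen's d, Cochran Q, exact McNemar) with study-level
    sensitivity and false-alarm tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
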