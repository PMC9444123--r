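Package: anodet
Title: Privacy-Preserving Anomaly Detection for Wearable Health Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects anomalous individuals in cohorts monitored by wearable
    sensors without exposing raw readings. Each student's N x M x K health
    tensor (students x criteria x time points) is reduced to compact M-bit
    health indexes by signed random-hyperplane projection; pairwise similarity
    is the number of index matches across q repetitions and p hash tables, and
    students with no similar peers at threshold T are flagged as anomalies.
    Includes a synthetic cohort generator with planted anomalies, a held-out
    prediction harness scored by MAE/RMSE against a user-based collaborative
    filtering baseline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
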