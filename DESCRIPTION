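Package: prodromewatch
Title: Single-Case Detection of Prodromal Sleep Disturbances in Bipolar Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A replicated single-case analysis pipeline for studying whether
    objectively measured sleep disturbances precede manic and depressive
    episodes in bipolar disorder. Scores nightly sleep variables (onset,
    offset, duration, onset latency, efficiency, wake after sleep onset,
    composite phase deviation) from epoch-level wrist-actigraphy counts and a
    morning sleep diary; detects mood episodes from weekly ASRM and IDS-SR
    scales combined with a daily Life Chart self-rating; selects symptom-quiet
    stable periods; flags extreme values with Shewhart individuals control
    charts; detects structural mean shifts by least-squares segmentation with
    a minimum segment size, a supF existence test and bootstrap confidence
    intervals for break dates; and combines both change mechanisms into
    per-variable prodromal change labels, a sleep-versus-mood temporal-order
    verdict and a prodromal-versus-stable event-rate comparison. A synthetic
    cohort generator with scripted episodes and injected disturbances
    provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
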