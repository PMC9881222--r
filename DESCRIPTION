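Package: sleepfp
Title: State-Dependent Fiber Photometry and Rodent Sleep Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-triggered analysis stack for fiber-photometry and
    biosensor recordings in behaving rodents. Provides rule-based sleep
    scoring from EEG/EMG (4-s epochs refined to 1-s labels, EMG-threshold
    micro-awakening detection), ratiometric (FRET) and single-channel
    sensor normalization (dR/R, dF/F, percent-of-baseline), windowed AUC
    and peak/trough quantification around optogenetic stimulations and
    vigilance-state transitions, session/group averaging under the
    study-design validity rules, and the nonparametric battery used in
    this field (exact Wilcoxon signed-rank and Mann-Whitney tests,
    Friedman and Kruskal-Wallis omnibus tests, Steel and Steel-Dwass
    post-hoc procedures). A seeded synthetic-recording generator with
    ground-truth annotations makes every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
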