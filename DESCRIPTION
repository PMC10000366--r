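Package: emofuse
Title: Bimodal EEG and Facial-Video Emotion Recognition with Deep CCA Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for three-class (happy / neutral / sad)
    emotion recognition from paired electroencephalography (EEG) recordings
    and facial video, following a two-stage design: redundant-frame
    elimination by frame differencing, EEG band-pass filtering with
    frontal/temporal electrode selection and 5-second windowing, a
    lightweight 1D convolutional feature extractor for EEG, an adapted
    residual-network (or tiny) backbone for facial frames, deep canonical
    correlation analysis (DCCA) feature-level fusion with a closed-form CCA
    oracle, decision-level baseline fusions (max rule, Choquet fuzzy
    integral with a Sugeno lambda-measure, adaptive rule, concatenation,
    kernel combination), and leave-one-subject-out evaluation. A synthetic
    paired-trial generator with tunable class separation and cross-modal
    correlation makes every stage testable without access to gated corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
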