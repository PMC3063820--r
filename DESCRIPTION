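Package: qpcrflux
Title: Relative Quantification and Turnover-Potential Scoring for qPCR
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete relative-quantification workflow for SYBR-green
    qPCR experiments: amplification-efficiency estimation from raw
    fluorescence curves by a window-of-linearity fit, Grubbs-test
    screening of technical triplicates, BestKeeper-style reference-gene
    stability ranking, efficiency-corrected expression ratios with
    randomization p-values and bootstrap intervals, 2^-ddCt normalized
    transcript amounts, and transcript-abundance x kcat turnover-potential
    scores for enzymes competing for a shared precursor pool. Includes a
    synthetic-data generator with known ground truth and a packaged
    fixture of published CT, primer-efficiency and enzyme-kinetics tables
    from a survey of terpene-metabolism genes in Artemisia annua tissues.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
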