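Package: cdktrace
Title: Single-Cell CDK Activity Traces, Reporter Quantification, and
    Cell-Cycle Commitment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying kinase translocation reporter (KTR)
    activities from single-cell time-lapse microscopy and for analysing
    cell-cycle commitment from the resulting traces. Includes a
    phenomenological simulator of the CDK4/6-Rb-E2F-CDK2 commitment circuit
    with perturbations (CDK4/6 inhibitor, DNA-damage pulse, mitogen
    withdrawal) and a virtual-microscopy renderer with ground-truth masks;
    nuclear segmentation with cytoplasmic-ring and whole-cell measurement
    regions; cytoplasm-to-nucleus ratio quantification with CDK2 cross-talk
    correction of the CDK4/6 reporter; top-hat RNA FISH puncta counting;
    frame-to-frame tracking by optimal linear assignment with gap bridging
    and live-to-fixed cell mapping; onset detection, proliferative fate
    classification, trace alignment, and logistic estimation of the CDK2
    commitment boundary; and population statistics (mixture/Otsu thresholds,
    sigmoidal time-course fits, binned activity maps, EdU/Hoechst phase
    gating, Welch tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    mclust,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
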