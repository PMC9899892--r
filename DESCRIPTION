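Package: densaug
Title: Density-Stratified Synthetic Augmentation and Evaluation for Mammographic Mass Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying density-stratified data augmentation in
    mammographic mass detection. Generates seedable two-view mammogram
    phantoms with controllable fibroglandular density and inserted masses,
    maps continuous breast-density measures (Volpara VBD, LIBRA percent
    density, ACR categories) to BI-RADS A-D, trains unpaired low-to-high
    density image translators built on a cycle-consistent adversarial
    objective, assembles 1:1 and 1:3 synthetic-to-real augmented training
    manifests, and evaluates the results with FROC curves and partial AUC
    over FPPI in (0,1), paired DeLong tests, Frechet-distance image-quality
    bounds, and reader-study ROC analysis. All randomness is seeded and the
    full pipeline runs at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    EBImage,
    pROC,
    withr
Config/testthat/edition: 3
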