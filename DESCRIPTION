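Package: thermopattern
Title: Thermal Pattern Discovery in Equid Infrared Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and cross-species comparison of surface thermal patterns in
    infrared thermography (IRT) images of horses and donkeys. Provides a portable
    text format for thermograms with region-of-interest (ROI) class maps, assembly
    of pixel samples for ROIs and groups of ROIs (GORs), subsampled one-sided
    Mann-Whitney-Wilcoxon testing, global difference matrices and per-animal local
    count matrices, stable-pattern detection, a six-class cross-species pattern
    taxonomy, individual-animal compliance scoring, per-animal feature extraction
    with a two-dimensional t-SNE embedding, rendering of thermal maps, histograms
    and boxplot summaries, and a synthetic thermogram generator emulating the
    statistical structure of the study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    graphics,
    grDevices,
    png,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
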