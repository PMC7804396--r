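Package: startlehab
Title: Model-Based Quantification of Startle Reflex Habituation in Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the habituation of the startle reflex in
    larval zebrafish from per-stimulus locomotor distances. Provides readers
    and validators for long-format tracking exports, descriptive behavioural
    measures (cumulative distance travelled, response probability, thresholded
    response counts), a first-order exponential habituation model with
    amplitude, offset and decay-constant extraction, a fish-level bootstrap
    for population parameters, the non-parametric comparison suite used in
    startle research (Wilcoxon signed-rank, Friedman with Dunn-Bonferroni
    post-hocs, Spearman rank correlation), and a synthetic-data generator with
    known ground truth for end-to-end validation of the pipeline.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
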