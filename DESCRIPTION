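Package: reporteval
Title: Stress-Testing NLP Metrics for Radiology Report Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing how much corpus-level natural-language metrics
    (BLEU, ROUGE-L, METEOR, CIDEr and CIDEr-D) and rule-based diagnostic label
    accuracy actually reward input-conditioning in chest X-ray report
    generation. Implements single-report unconditioned baselines (best
    retrieved training report, with exact fast searches, and a greedy n-gram
    report synthesizer), permutation unconditioning of a model's candidate
    reports, stratified normal/abnormal evaluation, n-gram diversity counts, a
    paired bootstrap significance test, and a synthetic generator of
    standardized radiology-report corpora with tunable input-conditioning so
    the whole pipeline is testable without clinical data.
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
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
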