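# reporteval

Tools for stress-testing how automatic radiology-report generation is
evaluated. Chest X-ray reports are so standardized — shared boilerplate
sentences, ~70% fully normal studies — that corpus-overlap metrics (BLEU,
ROUGE-L, METEOR, CIDEr-D) and even rule-extracted diagnostic label accuracy
can be gamed by an *unconditioned model*: a system that emits one fixed
report for every input image. `reporteval` implements the metrics, the
unconditioned baselines, the diagnostic labeler, a permutation procedure
that severs a model's input-dependence, a paired bootstrap significance
test, and a synthetic report generator with a tunable conditioning dial, so
the whole argument can be run, tested and extended without clinical data.

## What is implemented

**Metrics** (`metric_spec()`, `evaluate_metrics()`, `bleu()`, `rouge_l()`,
`meteor()`, `cider()`): corpus BLEU-K with clipped counts
`min(occ(w, r_i), occ(w, c_i))` and brevity penalty
`BP = min(1, exp(1 - n_R/n_C))`, in both the conventional geometric-mean
("coco") dialect and the summed-precision form
`BP · Σ_k precision_k` with token-count denominators ("paper" dialect);
ROUGE-L as the LCS F-score with β = 1.2; exact-match METEOR
`(1 − 0.5·CP³) · 10PR/(9P + R)`; CIDEr / CIDEr-D as tf-idf cosine
agreement over gram orders 1..K with the Gaussian length penalty, clipping
and ×10 scale. Diagnostic label accuracy uses a pluggable 14-category rule
lexicon (mention phrases, negation cues, 3-token window).

**Unconditioned baselines** (`baseline1_*()`, `baseline2()`): the
retrieval baseline `c = argmax_{r∈R} s(r, R)` with exhaustive search and
exact fast searches (k-gram occurrence-threshold tables for BLEU,
per-length tf-idf tables for CIDEr-D, positive-count tables for accuracy),
and the greedy synthesizer that selects the word multiset maximizing
clipped unigram matches at the mean reference length and joins fragments
along frequent 2-grams.

**Evaluation harness** (`permute_candidates()`, `stratified_evaluate()`,
`ngram_diversity()`, `bootstrap_compare()`): permutation unconditioning
with an audited plan, normal/abnormal stratified scoring with per-stratum
pooling, unique n-gram diversity counts, and a shifted-null paired
bootstrap test (B = 1000, percentile CIs, add-one-smoothed two-sided
p-values).

**Synthetic corpora** (`generator_config()`, `generate_references()`,
`simulate_model()`): template-bank chest X-ray reports over four
anatomical topics with ground-truth labels and a simulated generator whose
conditioning strength ρ runs from 0 (unconditioned) to 1 (perfect).

## Worked example

```r
library(reporteval)

config  <- generator_config(n_reports = 300, seed = 2024)
records <- generate_references(config)                      # references + true labels
model   <- simulate_model(records, rho = 0.5, noise = 0.05, seed = 7)

evaluate_metrics(model, c("bleu-1", "bleu-4", "rouge_l", "meteor", "cider-d"))
#> # A tibble: 5 × 4
#>   metric  dialect score     n
#> 1 bleu-1  coco    0.569   300
#> 2 bleu-4  coco    0.298   300
#> 3 rouge_l <NA>    0.486   300
#> 4 meteor  <NA>    0.532   300
#> 5 cider-d <NA>    1.31    300

b1 <- baseline1_bleu_fast(records, K = 4, seed = 11)        # one retrieved report
b1
#> <baseline_result> bleu-4 (coco) = 0.366592 (ties: 1 of 300 references, seed 11)
#>   report (34 tokens): frontal and lateral views of the chest were obtained the
#>   cardiac silhouette and mediastinal contours are within normal limits no focal
#>   consolidation is seen there is no pulmonary edema the bony structures are intact

fixed <- records
fixed$candidate <- rep(list(b1$report), nrow(records))      # same report for everyone
evaluate_metrics(fixed, c("bleu-1", "bleu-4", "rouge_l", "meteor", "cider-d"))
#> # A tibble: 5 × 4
#>   metric  dialect score     n
#> 1 bleu-1  coco    0.598   300
#> 2 bleu-4  coco    0.367   300
#> 3 rouge_l <NA>    0.531   300
#> 4 meteor  <NA>    0.593   300
#> 5 cider-d <NA>    1.86    300
```

One fixed, image-blind report outscores the partially conditioned
simulated model on *every* metric — the inflation this package exists to
expose. The same holds for diagnostic accuracy, and the bootstrap test
cannot tell the model from its own permuted (input-severed) variant:

```r
truth <- as.matrix(records[chexpert_categories()])
label_accuracy(extract_label_table(model, side = "candidate"), truth)
#> [1] 0.9528571
baseline1_accuracy_fast(records, seed = 1)$value
#> [1] 0.9590476

perm <- permute_candidates(model, seed = 3)
bootstrap_compare(records, model, perm, "bleu-1", B = 1000, seed = 5)
#> <bootstrap_outcome> bleu-1: delta = 0.016694 (A = 0.569203, B = 0.552509)
#>   1000 replicates over 300 records; 95% CI [-0.001541, 0.033541]; p = 0.06893
```

A δ of 0.017 BLEU-1 with p ≈ 0.07: permuting the candidates across inputs
barely moves the score. Result objects support `tidy()`, `glance()` and
`autoplot()`.

A thin command-line front-end ships in `exec/reporteval`
(`simulate`, `evaluate`, `stratify`, `permute`, `diversity`, `baseline1`,
`baseline2`, `bootstrap`).

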