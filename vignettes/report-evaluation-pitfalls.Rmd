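---
title: "Stress-testing NLP metrics for radiology report generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-testing NLP metrics for radiology report generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reporteval)
library(dplyr)
```

## The problem this package addresses

Automatic chest X-ray report generators are usually scored with
surface-overlap metrics borrowed from captioning and translation — BLEU,
ROUGE-L, METEOR, CIDEr-D — and, more recently, with diagnostic label
accuracy extracted by rule-based labelers. Radiology reports, however, are
extremely standardized: a handful of template-like sentences about heart
size, lungs, pleura, and bones covers most of the corpus, and roughly 70%
of screening reports describe no abnormality at all. That structure lets a
*single fixed report*, emitted identically for every image, score
competitively on all of these metrics — even on label accuracy — while
carrying no information whatsoever about the patient in front of the
machine.

`reporteval` packages the machinery needed to demonstrate, quantify and
probe this failure mode on any parallel corpus of reference and candidate
reports, and bundles a synthetic corpus generator so the entire pipeline is
testable without access to clinical data.

## Corpus representation and text cleaning

A corpus is a tibble with one row per record: `id`, `reference` (a
list-column of token vectors), optionally `candidate` and a `tag` stratum
label. Cleaning (`preprocess_text()`) lowercases, splits on every maximal
run of non-alphabetic characters and drops empty fragments; stop words are
kept, nothing is stemmed. Two consequences worth knowing:

* hyphenated words split (`"x-ray"` → `x`, `ray`), and tokens made of
  digits or punctuation vanish entirely;
* de-identification placeholders (`xxxx` and friends) are removed by
  default because they stand for redacted content, with a flag to keep
  them.

Cleaning is idempotent, so corpora written to JSON Lines / CSV / paired
text files and reloaded reproduce the same token sequences exactly.
Reports that come out empty after cleaning are retained (corpus sizes stay
stable) and every metric is defined for them: an empty candidate scores 0
and drives the brevity penalty to its `n_C = 0` convention of 0.

## The metrics, and why dialects matter

All metric configurations flow through `metric_spec()`.

**BLEU.** Clipped k-gram matches `min(occ(w, r), occ(w, c))` pooled over
the corpus under the brevity penalty `min(1, exp(1 - n_R / n_C))`. Two
dialects are exposed because the literature is genuinely split: the
conventional geometric-mean corpus BLEU with per-order gram denominators
(`dialect = "coco"`, the behaviour of the COCO caption evaluation toolkit
most papers actually ran) and the summed form `BP * sum_k precision_k`
with every precision over the total candidate *token* count
(`dialect = "paper"`), which some report-generation papers print. The two
rank systems differently; on identical corpora the coco dialect is exactly
1 while the summed dialect gives `sum_k (n_C - (k-1) N) / n_C` — slightly
below `K` because higher-order windows are fewer than tokens. Tests assert
each dialect against its own closed form.

**ROUGE-L.** Per-pair LCS F-score with recall weight `beta = 1.2`,
averaged over pairs; a pair with no common subsequence scores 0 (the 0/0
convention). The LCS is checked in the test suite against an independent
edit-distance oracle (`adist` with substitution cost 2).

**METEOR.** Exact surface-form unigram matching only — no stemming or
synonym tables, since cleaned radiology vocabulary is small and this keeps
the metric reproducible. Matched unigrams equal the clipped counts; chunks
are minimized by a greedy alignment that repeatedly takes the longest
common contiguous block, then counts maximal runs contiguous in both
reports. Score: `(1 - 0.5 * (chunks/m)^3) * 10PR / (9P + R)`.

**CIDEr / CIDEr-D.** tf-idf cosine agreement averaged over gram orders
1..K (default `K = 4`). Term frequency is normalized by the report's total
k-gram count; `idf = log(N / df)` with natural log and unseen grams
floored at `df = 1`. CIDEr-D adds the Gaussian length penalty
`exp(-(|c| - |r|)^2 / (2 sigma^2))` with `sigma = 6` tokens, clips
candidate weights at the reference's, and scales by 10. The squared length
difference is the standard form; a `length_penalty = "linear"` variant is
exposed for comparison with implementations that drop the square. The key
structural fact — proved in the tests — is that a gram occurring in
*every* reference has idf exactly 0 and contributes nothing, which is why
single-report baselines built from boilerplate score so poorly on CIDEr-D
while doing well everywhere else.

**Label accuracy.** A deliberately small rule engine stands in for full
clinical labelers: a category is positive when a mention phrase occurs
without a negation cue in the 3 tokens immediately before it; no-mention
means negative, and labels are binary (the uncertain/blank distinctions of
full labelers are out of scope). Accuracy is the fraction of
(report, category) cells where candidate and reference labels agree. A
`macro` flag averages per category instead, though for complete tables the
two are numerically identical. The 14 default category names follow the
standard chest X-ray finding list, and both the lexicon (YAML) and label
tables (CSV, `positive/negative` or `1/0`) are pluggable so externally
produced labels can be dropped in.

## Unconditioned baselines

`baseline1_exhaustive()` retrieves the training report maximizing any
configured metric as the universal candidate, breaking ties uniformly
under a seed. Because the naive search is `O(N^2)`, the package implements
the table-driven fast paths for the three metrics where they exist:

* **BLEU** — an occurrence-threshold table `ge[w][t]` (number of reports
  containing gram `w` at least `t` times) turns the corpus-pooled clipped
  count of any candidate into a sum over its own grams, so scoring is
  linear in report length;
* **CIDEr-D** — reference tf-idf tables are split by report length so the
  length penalty factors out per bucket, and the clipped inner products
  are served from an inverted gram index;
* **label accuracy** — per-category positive counts make a candidate's
  mean agreement a constant-time lookup.

Each fast path is required (and tested) to reproduce the exhaustive
objective *and tie set* exactly. Scores within relative `1e-9` of the
maximum are treated as tied; both search paths share the same pooled
arithmetic so BLEU ties match bit-for-bit, and the CIDEr tolerance absorbs
re-association of floating-point sums. METEOR and ROUGE-L are sequence
metrics with no table shortcut and are served by the exhaustive search
only.

`baseline2()` *synthesizes* a report instead: greedy word selection to the
mean reference length (rounded half up, so the emitted corpus avoids the
brevity penalty), then fragment joining along the most frequent 2-grams.
Greedy selection is provably optimal for total clipped unigram matches —
the marginal value of one more copy of a word never increases — and the
tests confirm this against brute-force enumeration at small scale. The
joining loop as classically written need not terminate when no joinable
fragment pair remains, so this implementation walks the 2-gram frequency
list once, joins while a pair exists (smallest fragment indices first),
and finally concatenates leftovers by descending leading-word frequency;
ties everywhere resolve by frequency, then lexicographically, making the
construction fully deterministic. The output conserves the selected
multiset and is generally ungrammatical — which is precisely the point: a
nonsense report can still top the BLEU table.

## Permutation unconditioning and the bootstrap test

`permute_candidates()` reassigns a model's candidates across records by a
uniform random permutation (identity allowed by default; an
`identity_allowed = FALSE` option exists for strict-inequality checks,
since a sampled identity would vacuously preserve scores). If scores
survive permutation, the model was not using its input.

`bootstrap_compare()` turns "survive" into a test: records are resampled
with replacement `B = 1000` times (default), each metric is recomputed on
the resampled set — pooled statistics like the brevity penalty included —
and the null distribution is the bootstrap distribution of
`delta = s(A) - s(B)` recentered at zero. The two-sided p-value carries
add-one smoothing, `(1 + #{|delta_b - mean| >= |delta_obs|}) / (B + 1)`.
Percentile intervals (linear interpolation) are reported both for the
delta and for each system's replicate scores. Implementation note: every
metric exposes per-record sufficient statistics plus an aggregator, so a
replicate is a cheap re-aggregation that is *identical* to rescoring the
materialized resampled corpus (the tests verify this equivalence
directly). Swapping the two systems under the same seed negates the delta
and leaves the p-value untouched.

## The synthetic corpus generator

The generator is first-class, tested code, not a fixture. It emulates the
features of screening chest X-ray corpora that drive the phenomenon:

* a shared opening sentence plus one sentence per topic (heart, lungs,
  pleura, bones) drawn from small template banks, giving heavy sentence
  overlap across reports and a mean length of ~32 tokens — controlled by
  the banks themselves, never by truncation;
* 70% of reports fully normal by default; abnormal reports draw at least
  one positive finding with per-category conditional rates (cardiomegaly
  0.35, consolidation 0.25, atelectasis 0.25, effusion 0.30, edema 0.20,
  fracture 0.15, pneumothorax 0.10 — chosen once as plausible relative
  prevalences, with effusion/cardiomegaly common and pneumothorax rare);
* negated findings phrased with the cues the bundled lexicon recognizes,
  and template sentences written so a negation never bleeds across a
  sentence boundary into the next finding's window;
* a per-record ground-truth label vector with the invariant
  `tag == "normal"` exactly when all labels are negative.

`simulate_model()` then emulates a generator whose input-dependence is a
dial: with probability `rho` a candidate is rendered from its own record's
true labels, otherwise from the label vector of a uniformly drawn record
(sampling a whole observed vector preserves finding co-occurrence, which
per-category independent draws would not). Word-level corruption at rate
`noise` substitutes in-vocabulary tokens so cleaning invariants survive.
At `rho = 1, noise = 0` extracted candidate labels reproduce the truth
exactly; at `rho = 0` the model is fully unconditioned and permutation
changes nothing statistically.

What passing tests on this generator do *not* show: real reports have
richer vocabulary, longer-range discourse structure, uncertainty
phrasings, and labeler disagreements that the toy lexicon cannot produce.
The synthetic results demonstrate the *mechanisms* — boilerplate-driven
metric inflation, idf-zeroing, permutation insensitivity — not clinical
effect sizes.

## Numerical choices and degenerate inputs

* Brevity penalty at `n_C = 0` is defined as 0; every metric returns 0 for
  an empty candidate pair.
* Argmax tie grouping uses relative tolerance `1e-9`.
* Geometric-mean BLEU returns 0 if any order has zero matches (the
  standard convention); the summed dialect degrades gracefully instead.
* CIDEr contributions with a zero-norm vector on either side are 0.
* `percentile_ci()` uses quantile type 7 (linear interpolation), so
  `percentile_ci(1:100, 0.05)` is `(3.475, 97.525)`.
* Stratified evaluation re-pools corpus statistics per stratum; CIDEr idf
  defaults to the global reference index with a per-stratum override.

## Problem sizes used in the shipped checks

The package's own verification runs at deliberately modest scale: fast
vs exhaustive search equivalence on 20 generated corpora of 30–200
reports; greedy-selection optimality by full enumeration on corpora with
at most 8 distinct words and target lengths up to 6; bootstrap calibration
with 500 Monte-Carlo null repetitions at `B = 500` on 40-record corpora
(observed rejection at the nominal 5% level must land in [0.03, 0.08]);
and conditioning recovery over 50 generator replicates of 100 records
each. The acceptance script (`scripts/acceptance.R`) regenerates a
400-record study end-to-end and writes its headline numbers as JSON.

## Known limitations

Single reference per candidate only (the evaluation setting this tooling
targets); no SPICE or embedding metrics; the labeler has no uncertainty
class; and no attempt is made to reproduce any external labeler's exact
outputs on real clinical text — the label-table readers are the adapter
point for that.
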