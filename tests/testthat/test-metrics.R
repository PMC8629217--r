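identical_corpus <- function(n = 6, seed = 3) {
  withr::with_seed(seed, {
    refs <- random_reports(n, vocab_size = 10, len_min = 4, len_max = 9)
    report_corpus(refs, candidate = refs)
  })
}

test_that("brevity penalty matches its closed form", {
  expect_equal(brevity_penalty(4, 4), 1)
  expect_equal(brevity_penalty(8, 4), 1)
  expect_equal(brevity_penalty(2, 4), exp(-1), tolerance = 1e-12)
  expect_equal(brevity_penalty(0, 4), 0)
  expect_error(brevity_penalty(-1, 4), "nonnegative")
})

test_that("BLEU dialects behave as defined on identical and disjoint corpora", {
  corpus <- identical_corpus()
  for (K in 1:4) expect_equal(bleu(corpus, K)$score, 1)
  # the summed-precision dialect with a shared token denominator: precision_k
  # on an identical corpus is (n_C - (k-1) N) / n_C, not 1
  n_C <- sum(lengths(corpus$candidate))
  N <- nrow(corpus)
  for (K in 1:3) {
    expected <- sum((n_C - (seq_len(K) - 1) * N) / n_C)
    expect_equal(bleu(corpus, K, dialect = "paper")$score, expected, tolerance = 1e-12)
  }
  disjoint <- report_corpus(list(c("a", "b", "c")), list(c("x", "y", "z")))
  expect_equal(bleu(disjoint, 1)$score, 0)
  expect_equal(bleu(disjoint, 1, "paper")$score, 0)
})

test_that("single-pair BLEU-1 matches the hand-computed clipped precision", {
  pair <- report_corpus(list(c("the", "cat")), list(c("the", "cat", "sat")))
  # n_C = 3 >= n_R = 2 so BP = 1; clipped unigram matches 2 of 3
  expect_equal(bleu(pair, 1, dialect = "paper")$score, 2 / 3, tolerance = 1e-12)
  expect_equal(bleu(pair, 1, dialect = "coco")$score, 2 / 3, tolerance = 1e-12)
  empty <- report_corpus(list(c("a", "b")), list(character(0)))
  expect_equal(bleu(empty, 1)$score, 0)
})

test_that("BLEU is invariant under record permutation and monotone in clipping", {
  withr::local_seed(23)
  refs <- random_reports(15, vocab_size = 8)
  cands <- random_reports(15, vocab_size = 8)
  corpus <- report_corpus(refs, cands)
  p <- sample.int(15)
  shuffled <- corpus[p, ]
  for (dialect in c("coco", "paper")) {
    expect_equal(bleu(shuffled, 4, dialect)$score, bleu(corpus, 4, dialect)$score,
                 tolerance = 1e-12)
  }
  # dropping candidate tokens never increases pooled clipped matches
  truncated <- report_corpus(refs, lapply(cands, function(x) x[-length(x)]))
  for (k in 1:2) {
    full <- sum(mapply(brute_clipped_matches, cands, refs, k))
    less <- sum(mapply(brute_clipped_matches, truncated$candidate, refs, k))
    expect_lte(less, full)
  }
})

test_that("ROUGE-L agrees with an independent LCS oracle and stays in [0, 1]", {
  expect_equal(rouge_l(identical_corpus(1))$score, 1)
  expect_equal(rouge_l(report_corpus(list(c("a", "b")), list(c("x"))))$score, 0)
  worked <- report_corpus(list(c("a", "b", "c")), list(c("a", "c")))
  expect_equal(rouge_l(worked)$score,
               (1 + 1.2^2) * 1 * (2 / 3) / (1.2^2 * 1 + 2 / 3), tolerance = 1e-12)
  withr::local_seed(31)
  refs <- random_reports(20, vocab_size = 6)
  cands <- random_reports(20, vocab_size = 6)
  for (i in seq_along(refs)) {
    expect_identical(reporteval:::lcs_length(cands[[i]], refs[[i]]),
                     lcs_oracle(cands[[i]], refs[[i]]))
  }
  scores <- tidy(rouge_l(report_corpus(refs, cands)))$score
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("METEOR matches direct evaluation of its formula", {
  # identical reports, 4 distinct tokens: one chunk over four matches
  four <- report_corpus(list(c("a", "b", "c", "d")), list(c("a", "b", "c", "d")))
  expect_equal(meteor(four)$score, 1 - 0.5 * (1 / 4)^3, tolerance = 1e-12)
  single <- report_corpus(list(c("a")), list(c("a")))
  expect_equal(meteor(single)$score, 0.5, tolerance = 1e-12)
  none <- report_corpus(list(c("a", "b")), list(c("x", "y")))
  expect_equal(meteor(none)$score, 0)
  # a gap splits the alignment into two chunks: c = [a, b, x, c, d] vs
  # r = [a, b, c, d]: m = 4, P = 4/5, R = 1, chunks = 2
  gap <- report_corpus(list(c("a", "b", "c", "d")), list(c("a", "b", "x", "c", "d")))
  p <- 4 / 5
  expected <- (1 - 0.5 * (2 / 4)^3) * 10 * p * 1 / (9 * p + 1)
  expect_equal(meteor(gap)$score, expected, tolerance = 1e-12)
  withr::local_seed(37)
  corpus <- report_corpus(random_reports(15), random_reports(15))
  expect_true(all(tidy(meteor(corpus))$score >= 0 & tidy(meteor(corpus))$score <= 1))
})

test_that("CIDEr rewards self-similarity and ignores universal grams", {
  withr::local_seed(41)
  # distinct references: every gram misses at least one report, idf > 0
  refs <- list(c("wa", "wb", "wc"), c("wd", "we", "wf"), c("wg", "wh", "wi"))
  self <- report_corpus(refs, candidate = refs)
  expect_equal(cider(self, K = 2, variant = "plain")$score, 1, tolerance = 1e-12)
  disjoint <- report_corpus(list(c("wa", "wb")), list(c("zz", "zq")))
  for (v in c("plain", "d")) expect_equal(cider(disjoint, 2, v)$score, 0)
  # a gram in every reference has idf 0 and adds nothing
  idx <- ngram_index(refs <- list(c("u", "wa"), c("u", "wb"), c("u", "wc")), 1)
  expect_equal(unname(idx$per_k[[1]]$idf["u"]), 0)
  corpus <- report_corpus(refs, candidate = list(c("u"), c("u"), c("u")))
  expect_equal(cider(corpus, K = 1, variant = "d")$score, 0)
  # per-pair CIDEr-D lands in [0, 10]
  sim <- synthetic_pair_corpus(n = 15)
  scores <- tidy(cider(sim))$score
  expect_true(all(scores >= 0 & scores <= 10))
})

test_that("evaluate_metrics is deterministic, ordered and validates names", {
  corpus <- identical_corpus()
  res <- evaluate_metrics(corpus)
  expect_identical(res$metric, c("bleu-1", "bleu-2", "bleu-3", "bleu-4",
                                 "rouge_l", "meteor", "cider-d"))
  expect_equal(res$score[1:5], rep(1, 5))
  expect_identical(evaluate_metrics(corpus), res)
  expect_equal(nrow(evaluate_metrics(corpus, character(0))), 0)
  expect_error(evaluate_metrics(corpus, "spice"), "Unknown metric")
})
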