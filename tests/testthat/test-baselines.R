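# Independent oracle for the retrieval objective under the summed-precision
# BLEU-1: direct double loop over the definition, sharing no code with the
# implementation.
oracle_universal_bleu1_paper <- function(cand, refs) {
  n <- length(refs)
  n_C <- n * length(cand)
  if (n_C == 0) return(0)
  n_R <- sum(lengths(refs))
  matches <- sum(vapply(refs, function(r) {
    sum(vapply(unique(cand), function(w) min(sum(cand == w), sum(r == w)), numeric(1)))
  }, numeric(1)))
  min(1, exp(1 - n_R / n_C)) * matches / n_C
}

test_that("exhaustive retrieval maximizes the metric over the training set", {
  refs <- list(c("wa", "wb", "wc"), c("wa", "wb"), c("wd", "we", "wf", "wa"))
  res <- baseline1_exhaustive(refs, metric_spec("bleu", K = 1, dialect = "paper"), seed = 1)
  oracle <- vapply(refs, oracle_universal_bleu1_paper, numeric(1), refs)
  expect_equal(res$value, max(oracle), tolerance = 1e-12)
  expect_identical(res$tie_ids, which(oracle >= max(oracle) - 1e-12))
  expect_true(any(vapply(refs, identical, logical(1), res$report)))
})

test_that("ties are the whole set on identical references and break by seed", {
  refs <- rep(list(c("wa", "wb", "wc")), 5)
  res <- baseline1_exhaustive(refs, "bleu-1", seed = 7)
  expect_equal(res$tie_set_size, 5)
  again <- baseline1_exhaustive(refs, "bleu-1", seed = 7)
  expect_identical(res$chosen_index, again$chosen_index)
  other <- baseline1_exhaustive(refs, "bleu-1", seed = 8)
  expect_true(other$chosen_index %in% res$tie_ids)
})

test_that("fast searches replicate the exhaustive search exactly", {
  withr::local_seed(19)
  refs <- random_reports(40, vocab_size = 10, len_min = 4, len_max = 12)
  for (dialect in c("coco", "paper")) {
    fast <- baseline1_bleu_fast(refs, K = 4, dialect = dialect, seed = 3)
    slow <- baseline1_exhaustive(refs, metric_spec("bleu", K = 4, dialect = dialect), seed = 3)
    expect_identical(fast$tie_ids, slow$tie_ids)
    expect_equal(fast$value, slow$value, tolerance = 1e-12)
    expect_identical(fast$report, slow$report)
  }
  fast <- baseline1_ciderd_fast(refs, seed = 3)
  slow <- baseline1_exhaustive(refs, "cider-d", seed = 3)
  expect_identical(fast$tie_ids, slow$tie_ids)
  expect_equal(fast$value, slow$value, tolerance = 1e-9)

  records <- generate_references(generator_config(n_reports = 50, seed = 21))
  fast <- baseline1_accuracy_fast(records, seed = 3)
  slow <- baseline1_exhaustive(records, "accuracy", seed = 3)
  expect_identical(fast$tie_ids, slow$tie_ids)
  expect_equal(fast$value, slow$value, tolerance = 1e-12)
})

test_that("accuracy retrieval scores follow the positive-count formula", {
  # labels: one category 70% negative; a candidate negative there agrees 0.7
  labs <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("a", "b")))
  labs[1:3, 1] <- TRUE
  refs <- rep(list(c("wa")), 10)
  res <- baseline1_accuracy_fast(refs, reference_labels = labs, seed = 1)
  # best vector is (FALSE, FALSE): (7 + 10) / 20
  expect_equal(res$value, 17 / 20)
  all_neg <- matrix(FALSE, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(baseline1_accuracy_fast(refs[1:4], all_neg)$value, 1)
})

test_that("greedy synthesis reconstructs a shared report and obeys the tie rule", {
  # identical references with distinct tokens: step 1 recovers the multiset,
  # step 2 the original ordering
  refs <- rep(list(c("wq", "wa", "wz", "wm")), 4)
  res <- baseline2(refs)
  expect_identical(res$report, c("wq", "wa", "wz", "wm"))
  expect_equal(res$value, 1)  # perfect BLEU-2
  # {[a, b], [a, c]}: n = 2; "a" covers both references, then the
  # lexicographically first of the tied {b, c}
  res2 <- baseline2(list(c("a", "b"), c("a", "c")))
  expect_identical(sort(res2$report), c("a", "b"))
})

test_that("synthesis output length is the rounded mean reference length", {
  withr::local_seed(29)
  for (rep in 1:5) {
    refs <- random_reports(sample(3:12, 1), vocab_size = 6, len_min = 1, len_max = 9)
    res <- baseline2(refs)
    expect_length(res$report, floor(mean(lengths(refs)) + 0.5))
  }
})

test_that("fragment joining conserves the greedily selected word multiset", {
  # independent re-implementation of the word-selection step
  step1_oracle <- function(refs, n) {
    words <- sort(unique(unlist(refs)))
    freq <- vapply(words, function(w) sum(unlist(refs) == w), numeric(1))
    cur <- setNames(rep(0, length(words)), words)
    out <- character(0)
    for (i in seq_len(n)) {
      gains <- vapply(words, function(w) {
        sum(vapply(refs, function(r) sum(r == w) > cur[[w]], logical(1)))
      }, numeric(1))
      w <- words[order(-gains, -freq, words)[1]]
      cur[[w]] <- cur[[w]] + 1
      out <- c(out, w)
    }
    out
  }
  withr::local_seed(43)
  for (rep in 1:5) {
    refs <- random_reports(8, vocab_size = 5, len_min = 2, len_max = 8)
    res <- baseline2(refs)
    n <- floor(mean(lengths(refs)) + 0.5)
    expect_identical(sort(res$report), sort(step1_oracle(refs, n)))
  }
})

test_that("step-1 word selection attains the brute-force clipped-match optimum", {
  total_clipped <- function(multiset, refs) {
    sum(vapply(refs, function(r) {
      sum(vapply(unique(multiset), function(w) {
        min(sum(multiset == w), sum(r == w))
      }, numeric(1)))
    }, numeric(1)))
  }
  withr::local_seed(47)
  for (rep in 1:8) {
    vocab <- make_vocab(sample(3:6, 1))
    refs <- lapply(seq_len(sample(3:6, 1)), function(i) {
      sample(vocab, sample(2:6, 1), replace = TRUE)
    })
    res <- baseline2(refs)
    n <- length(res$report)
    # enumerate all multisets of size n over the vocabulary
    counts <- as.matrix(expand.grid(rep(list(0:n), length(vocab))))
    counts <- counts[rowSums(counts) == n, , drop = FALSE]
    best <- max(apply(counts, 1, function(cnt) {
      total_clipped(rep(vocab, cnt), refs)
    }))
    expect_equal(total_clipped(res$report, refs), best)
  }
})
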