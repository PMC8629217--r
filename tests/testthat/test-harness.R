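test_that("permutation reassigns candidates but preserves everything else", {
  corpus <- synthetic_pair_corpus(n = 12, seed = 5)
  perm <- permute_candidates(corpus, seed = 2)
  plan <- attr(perm, "permutation_plan")
  expect_true(all(sort(plan$p) == seq_len(12)))
  expect_identical(perm$candidate, corpus$candidate[plan$p])
  expect_identical(perm$reference, corpus$reference)
  expect_identical(perm$id, corpus$id)
  # multisets of reports unchanged
  expect_setequal(vapply(perm$candidate, paste, character(1), collapse = " "),
                  vapply(corpus$candidate, paste, character(1), collapse = " "))
  expect_identical(permute_candidates(corpus[1, ], seed = 1)$candidate,
                   corpus$candidate[1])
  expect_error(permute_candidates(corpus["id"] |> dplyr::mutate(reference = corpus$reference)),
               "candidate")
  # no-identity option never returns the identity
  for (s in 1:20) {
    p <- attr(permute_candidates(corpus[1:2, ], seed = s, identity_allowed = FALSE),
              "permutation_plan")$p
    expect_identical(p, c(2L, 1L))
  }
})

test_that("a single-report candidate set scores identically under permutation", {
  records <- generate_references(generator_config(n_reports = 15, seed = 8))
  fixed <- baseline1_bleu_fast(records, K = 2, seed = 1)$report
  corpus <- records
  corpus$candidate <- rep(list(fixed), nrow(records))
  perm <- permute_candidates(corpus, seed = 99)
  specs <- list(metric_spec("bleu", K = 4), metric_spec("bleu", K = 4, dialect = "paper"),
                "rouge_l", "meteor", "cider-d", "accuracy")
  for (s in specs) {
    expect_identical(metric_score(perm, s)$score, metric_score(corpus, s)$score)
  }
})

test_that("stratified evaluation recomputes pooled statistics per stratum", {
  corpus <- synthetic_pair_corpus(n = 20, seed = 12)
  # single stratum: identical to the unstratified run
  one <- corpus
  one$tag <- "all"
  strat <- stratified_evaluate(one, c("bleu-2", "rouge_l"))
  flat <- evaluate_metrics(one, c("bleu-2", "rouge_l"))
  expect_equal(strat$score, flat$score, tolerance = 1e-12)

  # pair-averaged metrics: overall = size-weighted mean of stratum scores
  strat2 <- stratified_evaluate(corpus, c("rouge_l", "meteor"))
  flat2 <- evaluate_metrics(corpus, c("rouge_l", "meteor"))
  for (m in c("rouge_l", "meteor")) {
    sub <- dplyr::filter(strat2, .data$metric == m)
    pooled <- sum(sub$score * sub$n) / sum(sub$n)
    expect_equal(pooled, dplyr::filter(flat2, .data$metric == m)$score, tolerance = 1e-12)
  }
  untagged <- dplyr::select(corpus, -"tag")
  expect_error(stratified_evaluate(untagged, "rouge_l"), "tag")
})

test_that("strata with disjoint vocabularies do not interact", {
  a <- report_corpus(list(c("wa", "wb"), c("wb", "wa")),
                     candidate = list(c("wa", "wb"), c("wa", "wb")),
                     id = c("a1", "a2"), tag = c("g1", "g1"))
  b <- report_corpus(list(c("zc", "zd"), c("zd", "zc")),
                     candidate = list(c("zc", "zd"), c("zc", "zd")),
                     id = c("b1", "b2"), tag = c("g2", "g2"))
  both <- dplyr::bind_rows(a, b)
  joint <- stratified_evaluate(both, c("bleu-1", "rouge_l"), idf = "stratum")
  alone <- evaluate_metrics(a, c("bleu-1", "rouge_l"))
  g1 <- dplyr::filter(joint, .data$tag == "g1")
  expect_equal(g1$score, alone$score, tolerance = 1e-12)
})
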