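test_that("generation is deterministic under a seed and tags match labels", {
  cfg <- generator_config(n_reports = 40, seed = 33)
  a <- generate_references(cfg)
  b <- generate_references(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$tag, b$tag)
  labs <- as.matrix(a[chexpert_categories()])
  expect_identical(a$tag == "normal", unname(rowSums(labs) == 0))
  # a different seed changes the draw
  expect_false(identical(generate_references(cfg, seed = 34)$reference, a$reference))
})

test_that("normal_fraction = 1 yields only normal records", {
  recs <- generate_references(generator_config(n_reports = 30, normal_fraction = 1, seed = 1))
  expect_true(all(recs$tag == "normal"))
  expect_false(any(as.matrix(recs[chexpert_categories()])))
})

test_that("the observed normal fraction concentrates near its target", {
  recs <- generate_references(generator_config(n_reports = 2000, seed = 55))
  expect_lt(abs(mean(recs$tag == "normal") - 0.70), 0.03)
  # mean report length sits in the standardized-report regime the banks target
  expect_gt(mean(lengths(recs$reference)), 25)
  expect_lt(mean(lengths(recs$reference)), 40)
})

test_that("reference reports decode to their own true labels", {
  recs <- generate_references(generator_config(n_reports = 150, seed = 77))
  extracted <- extract_label_table(recs, side = "reference")
  expect_equal(label_accuracy(extracted, as.matrix(recs[chexpert_categories()])), 1)
})

test_that("a perfectly conditioned noiseless generator round-trips labels", {
  recs <- generate_references(generator_config(n_reports = 80, seed = 91))
  sim <- simulate_model(recs, rho = 1, noise = 0, seed = 5)
  extracted <- extract_label_table(sim, side = "candidate")
  expect_equal(label_accuracy(extracted, as.matrix(recs[chexpert_categories()])), 1)
})

test_that("label accuracy rises with conditioning strength", {
  accs <- vapply(c(0, 0.5, 1), function(rho) {
    mean(vapply(1:8, function(rep) {
      recs <- generate_references(generator_config(n_reports = 120, seed = 100 + rep))
      sim <- simulate_model(recs, rho = rho, noise = 0.02, seed = 200 + rep)
      label_accuracy(extract_label_table(sim, side = "candidate"),
                     as.matrix(recs[chexpert_categories()]))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(accs[[1]], accs[[2]])
  expect_lt(accs[[2]], accs[[3]])
})

test_that("an unconditioned generator is no better than the accuracy retrieval baseline", {
  recs <- generate_references(generator_config(n_reports = 150, seed = 121))
  sim <- simulate_model(recs, rho = 0, noise = 0, seed = 6)
  sim_acc <- label_accuracy(extract_label_table(sim, side = "candidate"),
                            as.matrix(recs[chexpert_categories()]))
  b1 <- baseline1_accuracy_fast(recs, seed = 7)
  expect_gte(b1$value, sim_acc)
})

test_that("single-report baselines have no more unique n-grams than references", {
  recs <- generate_references(generator_config(n_reports = 60, seed = 131))
  b1 <- baseline1_bleu_fast(recs, K = 4, seed = 1)
  refs_div <- ngram_diversity(recs, n_values = 1:4)
  base_div <- ngram_diversity(list(b1$report), n_values = 1:4)
  expect_true(all(base_div$unique_ngrams <= refs_div$unique_ngrams))
})

test_that("word corruption keeps tokens in-vocabulary and cleaning-valid", {
  recs <- generate_references(generator_config(n_reports = 25, seed = 141))
  sim <- simulate_model(recs, rho = 0.5, noise = 0.5, seed = 9)
  vocab <- attr(recs, "generator_config")$templates$vocabulary
  for (cand in sim$candidate) {
    expect_true(all(grepl("^[a-z]+$", cand)))
    expect_true(all(cand %in% vocab))
  }
})
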