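# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness seed it locally so the suite is deterministic.

# Alphabetic vocabulary of m tokens: "wa", "wb", ...
make_vocab <- function(m) {
  stopifnot(m <= 26 * 26)
  paste0("w", c(outer(letters, letters, paste0)))[seq_len(m)]
}

# n random reports over a small vocabulary (call under a seed).
random_reports <- function(n, vocab_size = 12, len_min = 3, len_max = 10) {
  vocab <- make_vocab(vocab_size)
  lapply(seq_len(n), function(i) {
    sample(vocab, sample(len_min:len_max, 1), replace = TRUE)
  })
}

# Small synthetic chest X-ray corpus with candidates from the simulated
# generator.
synthetic_pair_corpus <- function(n = 30, rho = 0.5, noise = 0.05, seed = 1) {
  records <- generate_references(generator_config(n_reports = n, seed = seed))
  simulate_model(records, rho = rho, noise = noise, seed = seed + 1)
}

# Independent per-pair clipped-match oracle: plain double loop over grams,
# no shared code with ngram_counts()/pair_clipped_matches().
brute_clipped_matches <- function(cand, ref, k) {
  gram_at <- function(x, i) paste(x[i:(i + k - 1)], collapse = "\r")
  if (length(cand) < k || length(ref) < k) return(0L)
  cand_grams <- vapply(seq_len(length(cand) - k + 1), gram_at, character(1), x = cand)
  ref_grams <- vapply(seq_len(length(ref) - k + 1), gram_at, character(1), x = ref)
  total <- 0L
  for (g in unique(cand_grams)) {
    total <- total + min(sum(cand_grams == g), sum(ref_grams == g))
  }
  total
}

# Independent LCS oracle via generalized edit distance: with substitution
# cost 2 and unit indels, distance = |a| + |b| - 2 * LCS.
lcs_oracle <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  u <- unique(c(a, b))
  stopifnot(length(u) <= 400)
  pool <- intToUtf8(seq(1000, 999 + length(u)), multiple = TRUE)
  sa <- paste(pool[match(a, u)], collapse = "")
  sb <- paste(pool[match(b, u)], collapse = "")
  d <- utils::adist(sa, sb, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
  as.integer((length(a) + length(b) - d) / 2)
}
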