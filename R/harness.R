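#' Sever input-conditioning by permuting candidates
#'
#' Reassigns the candidate reports across records by a uniform random
#' permutation, leaving references, ids and tags untouched. If a generation
#' model truly uses its input, scores should drop after permutation; if they
#' do not, the model is behaving like an unconditioned one. The sampled
#' permutation is recorded in the `"permutation_plan"` attribute of the
#' result for audit.
#'
#' @param corpus A corpus tibble with candidates.
#' @param seed Integer seed (optional).
#' @param identity_allowed Accept the identity permutation if sampled
#'   (default `TRUE`, plain uniform sampling)? With `FALSE` and more than
#'   one record, sampling repeats until the permutation moves something.
#' @return The corpus with permuted candidates; the plan (permutation, seed,
#'   flag) is attached as attribute `"permutation_plan"`.
#' @examples
#' corpus <- report_corpus(c("a b", "c d"), c("a b", "c d"))
#' permute_candidates(corpus, seed = 1)
#' @export
permute_candidates <- function(corpus, seed = NULL, identity_allowed = TRUE) {
  check_corpus(corpus, require_candidate = TRUE)
  m <- nrow(corpus)
  p <- with_seed_if(seed, {
    p <- sample.int(m)
    if (!identity_allowed && m > 1) {
      while (all(p == seq_len(m))) p <- sample.int(m)
    }
    p
  })
  out <- corpus
  out$candidate <- corpus$candidate[p]
  attr(out, "permutation_plan") <- list(p = p, seed = seed,
                                        identity_allowed = identity_allowed)
  out
}

#' Evaluate metrics within normal/abnormal strata
#'
#' Splits the corpus by its `tag` column and evaluates every configured
#' metric within each stratum independently: corpus-pooled statistics (the
#' brevity penalty, pooled precisions) are recomputed per stratum. CIDEr idf
#' weights default to a single index over the *whole* corpus's references
#' (`idf = "global"`); `idf = "stratum"` re-derives them per stratum.
#'
#' @inheritParams evaluate_metrics
#' @param idf `"global"` (default) or `"stratum"`, for CIDEr configurations
#'   without an explicit index.
#' @return A tibble with one row per (tag, metric): `tag`, `metric`,
#'   `dialect`, `score`, `n`.
#' @export
stratified_evaluate <- function(corpus,
                                metrics = c("bleu-1", "bleu-2", "bleu-3", "bleu-4",
                                            "rouge_l", "meteor", "cider-d"),
                                lexicon = NULL, idf = c("global", "stratum")) {
  idf <- match.arg(idf)
  check_corpus(corpus, require_candidate = TRUE, require_tag = TRUE)
  specs <- lapply(as.list(metrics), as_metric_spec)
  if (idf == "global" && length(specs)) {
    needs <- vapply(specs, function(s) s$metric == "cider" && is.null(s$index), logical(1))
    if (any(needs)) {
      kmax <- max(vapply(specs[needs], `[[`, integer(1), "K"))
      global_index <- ngram_index(corpus, k_max = kmax)
      specs[needs] <- lapply(specs[needs], function(s) { s$index <- global_index; s })
    }
  }
  corpus |>
    dplyr::group_by(.data$tag) |>
    dplyr::group_modify(function(sub, key) {
      evaluate_metrics(sub, metrics = specs, lexicon = lexicon)
    }) |>
    dplyr::ungroup()
}
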