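#' Count the k-grams of a report
#'
#' Sliding-window contiguous k-grams; the total multiplicity is
#' `max(0, length(tokens) - k + 1)`. Grams are keyed by their space-joined
#' tokens.
#'
#' @param tokens A report (character vector of tokens).
#' @param k Gram order, an integer >= 1.
#' @return A named integer vector of gram counts (empty when the report is
#'   shorter than `k`).
#' @examples
#' ngram_counts(c("a", "b", "a"), 2)
#' @export
ngram_counts <- function(tokens, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) abort("`k` must be an integer >= 1.")
  n <- length(tokens)
  if (n < k) return(setNames(integer(0), character(0)))
  grams <- tokens[seq_len(n - k + 1)]
  if (k > 1) {
    for (j in 2:k) grams <- paste(grams, tokens[j:(n - k + j)])
  }
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

#' Index the k-grams of a reference corpus
#'
#' Precomputes, for every gram order `k = 1..k_max`: corpus occurrence
#' counts, document frequencies, tf-idf inverse-document-frequency weights
#' (`idf = log(N / df)`, natural log, so a gram present in every report gets
#' idf 0), and an occurrence-threshold table `ge[[w]][t] = ` number of reports
#' containing gram `w` at least `t` times. The threshold table is what makes
#' the fast retrieval baselines possible: the corpus-pooled clipped match
#' count of a candidate that contains `w` `m` times is
#' `sum(ge[[w]][1:m])`, so a candidate's pooled BLEU statistics cost time
#' proportional to its own length, not to the corpus size.
#'
#' @param references A corpus tibble, raw character vector, or list of token
#'   vectors.
#' @param k_max Highest gram order to index (default 4).
#' @return An object of class `ngram_index`.
#' @export
ngram_index <- function(references, k_max = 4) {
  refs <- reports_from(references, side = "reference")
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 1) abort("`k_max` must be an integer >= 1.")
  N <- length(refs)
  per_k <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    tabs <- lapply(refs, ngram_counts, k = k)
    counts <- unlist(tabs, use.names = TRUE)
    if (is.null(counts)) counts <- setNames(integer(0), character(0))
    by_gram <- split(unname(counts), names(counts))
    df <- lengths(by_gram)
    occ <- vapply(by_gram, sum, integer(1))
    ge <- lapply(by_gram, function(v) {
      vapply(seq_len(max(v)), function(t) sum(v >= t), integer(1))
    })
    per_k[[k]] <- list(occ = occ, df = df, idf = log(N / df), ge = ge)
  }
  structure(
    list(
      N = N, k_max = k_max,
      lengths = lengths(refs),
      total_tokens = sum(lengths(refs)),
      per_k = per_k
    ),
    class = "ngram_index"
  )
}

#' @export
print.ngram_index <- function(x, ...) {
  cat(sprintf("<ngram_index> %d reports, %d tokens, k = 1..%d\n",
              x$N, x$total_tokens, x$k_max))
  for (k in seq_len(x$k_max)) {
    cat(sprintf("  %d-grams: %d distinct\n", k, length(x$per_k[[k]]$occ)))
  }
  invisible(x)
}

# Pooled clipped match count, over all indexed references, of a candidate
# whose k-gram counts are `counts`: sum_i sum_w min(occ(w, r_i), occ(w, c)).
index_clipped_matches <- function(index, counts, k) {
  tab <- index$per_k[[k]]$ge
  if (!length(counts)) return(0L)
  hit <- names(counts) %in% names(tab)
  if (!any(hit)) return(0L)
  sum(vapply(which(hit), function(i) {
    ge <- tab[[names(counts)[i]]]
    sum(ge[seq_len(min(counts[[i]], length(ge)))])
  }, integer(1)))
}

# tf-idf weight vector of a report for gram order k, with term frequency
# normalized by the report's total k-gram count and unseen grams floored at
# document frequency 1.
tfidf_vector <- function(tokens, k, index) {
  counts <- ngram_counts(tokens, k)
  if (!length(counts)) return(setNames(numeric(0), character(0)))
  df <- index$per_k[[k]]$df[names(counts)]
  df[is.na(df)] <- 1L
  tf <- counts / sum(counts)
  setNames(as.numeric(tf * log(index$N / df)), names(counts))
}

# Accept a corpus tibble, a list of reports, or raw text; return report list.
reports_from <- function(x, side = "reference") {
  if (is.data.frame(x)) return(corpus_side(x, side))
  out <- as_report_list(x)
  if (is.null(out) || !length(out)) abort("At least one report is required.")
  out
}

#' Count distinct n-grams pooled over a report set
#'
#' Diversity statistic for comparing generated reports against references: a
#' model that emits near-identical reports has far fewer unique n-grams than
#' the ground truth, and a single-report baseline has at most one report's
#' worth.
#'
#' @param reports A corpus tibble (uses `side`), raw character vector, or
#'   list of token vectors.
#' @param n_values Integer gram orders to count (default `1:4`).
#' @param side Which corpus side to use when `reports` is a corpus tibble.
#' @return A tibble with columns `n` and `unique_ngrams`.
#' @examples
#' ngram_diversity(list(c("a", "b", "a")), n_values = 1:2)
#' @export
ngram_diversity <- function(reports, n_values = 1:4, side = "reference") {
  reps <- reports_from(reports, side = side)
  n_values <- as.integer(n_values)
  if (any(is.na(n_values) | n_values < 1)) abort("`n_values` must be integers >= 1.")
  tibble(
    n = n_values,
    unique_ngrams = vapply(n_values, function(k) {
      length(unique(unlist(lapply(reps, function(r) names(ngram_counts(r, k))),
                           use.names = FALSE)))
    }, integer(1))
  )
}
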