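#' @title Single-report unconditioned baselines
#' @description
#' A *single-report unconditioned model* emits one fixed report for every
#' input, ignoring the image entirely. Two constructions are provided:
#'
#' * **Retrieval (baseline 1)** — the training report that maximizes a
#'   chosen corpus metric when used as the universal candidate,
#'   `argmax_{r in R} s(r, R)`, with ties broken uniformly at random under a
#'   seed. [baseline1_exhaustive()] scores every report directly (O(N^2));
#'   [baseline1_bleu_fast()], [baseline1_ciderd_fast()] and
#'   [baseline1_accuracy_fast()] compute identical objectives from
#'   precomputed corpus tables.
#' * **Greedy synthesis (baseline 2)** — [baseline2()] builds a brand-new
#'   report: a multiset of the words with the most unmatched reference
#'   occurrences (targeting unigram precision at the mean reference length),
#'   then joins words into fragments along the corpus's most frequent
#'   2-grams (targeting bigram precision).
#'
#' These baselines exist to be *compared against*: a model that truly uses
#' its input should beat them.
#' @name unconditioned_baselines
NULL

new_baseline_result <- function(tokens, objective, value, tie_ids, chosen, seed, n_refs) {
  structure(
    list(report = tokens, objective = objective, value = as.numeric(value),
         tie_ids = tie_ids, tie_set_size = length(tie_ids),
         chosen_index = chosen, seed = seed, n_references = n_refs),
    class = "baseline_result"
  )
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> %s = %.6f (ties: %d of %d references, seed %s)\n",
              x$objective, x$value, x$tie_set_size, x$n_references,
              x$seed %||% "none"))
  cat(sprintf("  report (%d tokens): %s\n", length(x$report),
              paste(x$report, collapse = " ")))
  invisible(x)
}

#' @method tidy baseline_result
#' @export
tidy.baseline_result <- function(x, ...) {
  tibble(position = seq_along(x$report), token = x$report)
}

#' @method glance baseline_result
#' @export
glance.baseline_result <- function(x, ...) {
  tibble(objective = x$objective, value = x$value,
         tie_set_size = x$tie_set_size, report_length = length(x$report),
         n_references = x$n_references,
         report = paste(x$report, collapse = " "))
}

# Indices within `tol` (relative) of the maximum; the tie set of an argmax.
tie_set <- function(scores, tol = 1e-9) {
  m <- max(scores)
  which(scores >= m - tol * max(1, abs(m)))
}

pick_tied <- function(tie_ids, seed) {
  with_seed_if(seed, tie_ids[[sample.int(length(tie_ids), 1L)]])
}

finish_baseline1 <- function(refs, scores, objective, seed) {
  ties <- tie_set(scores)
  chosen <- pick_tied(ties, seed)
  new_baseline_result(refs[[chosen]], objective, scores[[chosen]], ties, chosen,
                      seed, length(refs))
}

#' Retrieval baseline by exhaustive search
#'
#' Scores every training report as the universal candidate under `metric`
#' and retrieves a random maximizer. This is the reference implementation
#' the fast searches are checked against; it costs one full corpus
#' evaluation per training report.
#'
#' @param references A corpus tibble, raw character vector, or list of token
#'   vectors (the training reports `R`).
#' @param metric A [metric_spec()], shorthand string, or a function
#'   `f(candidate_tokens, reference_list) -> numeric` for custom objectives.
#' @param seed Integer seed for tie-breaking (optional).
#' @return A `baseline_result`: the retrieved report, its objective value,
#'   and the tie set.
#' @examples
#' refs <- list(c("the", "heart", "is", "normal"), c("the", "lungs", "are", "clear"))
#' baseline1_exhaustive(refs, "bleu-1", seed = 1)
#' @export
baseline1_exhaustive <- function(references, metric, seed = NULL) {
  refs <- reports_from(references)
  n <- length(refs)
  if (is.function(metric)) {
    scores <- vapply(refs, metric, numeric(1), refs)
    return(finish_baseline1(refs, scores, "custom", seed))
  }
  spec <- as_metric_spec(metric)
  if (spec$metric == "cider" && is.null(spec$index)) {
    spec$index <- ngram_index(refs, k_max = spec$K)
  }
  if (spec$metric == "accuracy") {
    lex <- spec$lexicon %||% default_lexicon()
    labs <- label_matrix_from_reports(refs, lex)
    scores <- vapply(seq_len(n), function(i) {
      mean(vapply(seq_len(n), function(j) mean(labs[i, ] == labs[j, ]), numeric(1)))
    }, numeric(1))
    return(finish_baseline1(refs, scores, spec$label, seed))
  }
  # Per-pair scoring with reference-side tables hoisted out of the loop.
  if (spec$metric == "bleu") {
    K <- spec$K
    ref_tabs <- lapply(seq_len(K), function(k) lapply(refs, ngram_counts, k = k))
    n_R <- sum(lengths(refs))
    scores <- vapply(refs, function(cand) {
      cand_tabs <- lapply(seq_len(K), function(k) ngram_counts(cand, k))
      matches <- vapply(seq_len(K), function(k) {
        sum(vapply(ref_tabs[[k]], pair_clipped_matches,
                   integer(1), cand_counts = cand_tabs[[k]]))
      }, integer(1))
      score_pooled_bleu(matches,
                        cand_grams = n * pmax(0L, length(cand) - seq_len(K) + 1L),
                        n_C = n * length(cand), n_R = n_R, spec = spec)
    }, numeric(1))
    return(finish_baseline1(refs, scores, sprintf("%s (%s)", spec$label, spec$dialect), seed))
  }
  if (spec$metric == "cider") {
    vecs <- lapply(seq_len(spec$K), function(k) lapply(refs, tfidf_vector, k = k, index = spec$index))
    norms <- lapply(vecs, function(vk) vapply(vk, function(v) sqrt(sum(v^2)), numeric(1)))
    scores <- vapply(seq_along(refs), function(ci) {
      cand <- refs[[ci]]
      total <- 0
      for (k in seq_len(spec$K)) {
        gc <- vecs[[k]][[ci]]
        ngc <- norms[[k]][[ci]]
        if (ngc == 0) next
        for (j in seq_along(refs)) {
          gr <- vecs[[k]][[j]]
          ngr <- norms[[k]][[j]]
          if (ngr == 0) next
          common <- intersect(names(gc), names(gr))
          if (!length(common)) next
          if (spec$variant == "plain") {
            total <- total + sum(gc[common] * gr[common]) / (ngc * ngr)
          } else {
            pen <- cider_length_penalty(length(cand), length(refs[[j]]),
                                        spec$sigma, spec$length_penalty)
            total <- total + 10 * pen *
              sum(pmin(gc[common], gr[common]) * gr[common]) / (ngc * ngr)
          }
        }
      }
      total / (spec$K * n)
    }, numeric(1))
    return(finish_baseline1(refs, scores, spec$label, seed))
  }
  # Sequence-matching metrics (ROUGE-L, METEOR) have no table speed-up;
  # score each report pairwise.
  scores <- vapply(refs, function(cand) {
    mean(vapply(refs, function(r) {
      switch(spec$metric,
             rouge_l = pair_rouge_l(cand, r, spec$beta),
             meteor = pair_meteor(cand, r))
    }, numeric(1)))
  }, numeric(1))
  finish_baseline1(refs, scores, spec$label, seed)
}

# Pooled BLEU score from pooled clipped matches; shared by exhaustive and
# fast paths so both compute bit-identical arithmetic.
score_pooled_bleu <- function(matches, cand_grams, n_C, n_R, spec) {
  if (n_C == 0) return(0)
  bp <- brevity_penalty(n_C, n_R)
  if (spec$dialect == "paper") {
    bp * sum(matches) / n_C
  } else {
    if (any(cand_grams == 0) || any(matches == 0)) return(0)
    bp * exp(mean(log(matches / cand_grams)))
  }
}

#' Retrieval baseline with the k-gram table speed-up (BLEU)
#'
#' Builds the corpus k-gram occurrence-threshold table once, after which the
#' pooled clipped match counts of any candidate — and hence its corpus BLEU
#' as the universal candidate — cost time proportional to the candidate's
#' length. Returns exactly the result of [baseline1_exhaustive()] with the
#' same BLEU configuration and seed.
#'
#' @inheritParams baseline1_exhaustive
#' @param K BLEU order (default 4).
#' @param dialect `"coco"` or `"paper"`.
#' @return A `baseline_result`.
#' @export
baseline1_bleu_fast <- function(references, K = 4, dialect = c("coco", "paper"),
                                seed = NULL) {
  spec <- metric_spec("bleu", K = K, dialect = match.arg(dialect))
  refs <- reports_from(references)
  n <- length(refs)
  index <- ngram_index(refs, k_max = spec$K)
  n_R <- index$total_tokens
  scores <- vapply(refs, function(cand) {
    matches <- vapply(seq_len(spec$K), function(k) {
      index_clipped_matches(index, ngram_counts(cand, k), k)
    }, integer(1))
    score_pooled_bleu(matches,
                      cand_grams = n * pmax(0L, length(cand) - seq_len(spec$K) + 1L),
                      n_C = n * length(cand), n_R = n_R, spec = spec)
  }, numeric(1))
  finish_baseline1(refs, scores, sprintf("%s (%s)", spec$label, spec$dialect), seed)
}

#' Retrieval baseline with per-length tables (CIDEr-D)
#'
#' CIDEr-D's length penalty couples a candidate to each reference's length,
#' so the corpus tables are split by reference length: for each length
#' bucket the references' clipped tf-idf inner products are served from an
#' inverted gram index, and a candidate's mean CIDEr-D is assembled as a
#' penalty-weighted sum over buckets. Equivalent to the exhaustive search.
#'
#' @inheritParams baseline1_exhaustive
#' @param K Maximum gram order (default 4).
#' @param sigma Length-penalty scale (default 6).
#' @param length_penalty `"squared"` (standard) or `"linear"`.
#' @return A `baseline_result`.
#' @export
baseline1_ciderd_fast <- function(references, K = 4, sigma = 6,
                                  length_penalty = c("squared", "linear"),
                                  seed = NULL) {
  spec <- metric_spec("cider", K = K, variant = "d", sigma = sigma,
                      length_penalty = match.arg(length_penalty))
  refs <- reports_from(references)
  n <- length(refs)
  index <- ngram_index(refs, k_max = K)
  lens <- lengths(refs)
  buckets <- split(seq_len(n), lens)
  # Per (bucket, k): gram -> the references' tf-idf weights and their
  # norm-scaled versions, so a clipped inner product against any candidate
  # weight `a` is sum(g[g <= a] * gn[g <= a]) + a * sum(gn[g > a]).
  tables <- lapply(buckets, function(ids) {
    lapply(seq_len(K), function(k) {
      vk <- unname(lapply(refs[ids], tfidf_vector, k = k, index = index))
      nk <- vapply(vk, function(v) sqrt(sum(v^2)), numeric(1))
      keep <- nk > 0
      if (!any(keep)) return(list())
      g <- unlist(vk[keep], use.names = TRUE)
      gn <- unlist(lapply(which(keep), function(i) vk[[i]] / nk[[i]]), use.names = FALSE)
      split(data.frame(g = unname(g), gn = gn), names(g))
    })
  })
  bucket_lens <- as.integer(names(buckets))
  scores <- vapply(refs, function(cand) {
    total <- 0
    for (k in seq_len(K)) {
      gc <- tfidf_vector(cand, k, index)
      ngc <- sqrt(sum(gc^2))
      if (ngc == 0) next
      for (b in seq_along(buckets)) {
        tab <- tables[[b]][[k]]
        if (!length(tab)) next
        hit <- names(gc)[names(gc) %in% names(tab)]
        if (!length(hit)) next
        s <- sum(vapply(hit, function(w) {
          a <- gc[[w]]
          e <- tab[[w]]
          below <- e$g <= a
          sum(e$g[below] * e$gn[below]) + a * sum(e$gn[!below])
        }, numeric(1)))
        pen <- cider_length_penalty(length(cand), bucket_lens[[b]],
                                    sigma, spec$length_penalty)
        total <- total + 10 * pen * s / ngc
      }
    }
    total / (K * n)
  }, numeric(1))
  finish_baseline1(refs, scores, spec$label, seed)
}

#' Retrieval baseline with precomputed labels (diagnostic accuracy)
#'
#' With every reference's label vector precomputed, per-category positive
#' counts make a candidate's mean label accuracy against the whole corpus a
#' constant-time lookup: a candidate positive in a category agrees with the
#' `p` positive references there, a negative one with the other `N - p`.
#'
#' @inheritParams baseline1_exhaustive
#' @param reference_labels Optional label table aligned with `references`
#'   (tibble, matrix, or list of named logical vectors); extracted with
#'   `lex` when omitted.
#' @param lex Lexicon used when labels must be extracted.
#' @return A `baseline_result`.
#' @export
baseline1_accuracy_fast <- function(references, reference_labels = NULL,
                                    lex = default_lexicon(), seed = NULL) {
  refs <- reports_from(references)
  n <- length(refs)
  labs <- if (is.null(reference_labels)) {
    label_matrix_from_reports(refs, lex)
  } else {
    as_label_matrix(reference_labels)
  }
  if (nrow(labs) != n) abort("`reference_labels` must have one row per reference.")
  pos <- colSums(labs)
  ncat <- ncol(labs)
  scores <- vapply(seq_len(n), function(i) {
    sum(ifelse(labs[i, ], pos, n - pos)) / (n * ncat)
  }, numeric(1))
  finish_baseline1(refs, scores, "accuracy", seed)
}

#' Greedy single-report synthesis (word selection + fragment joining)
#'
#' Builds one report of length `n` = the mean reference length (rounded half
#' up, so emitting it once per reference avoids the brevity penalty):
#'
#' 1. *Word selection* — repeatedly add the word with unmatched occurrences
#'    in the largest number of references, i.e.
#'    `argmax_w #\{r : occ(w, r) > occ(w, c)\}`; this greedily maximizes the
#'    total clipped unigram matches (the marginal gain of one more copy of a
#'    word never increases, so greedy is exact).
#' 2. *Fragment joining* — walk the corpus 2-grams once in descending
#'    frequency; for 2-gram `(a, b)`, while some fragment ends in `a` and a
#'    different one starts with `b`, join them. Remaining fragments are
#'    concatenated in descending frequency of their leading word. Joining
#'    only reorders: the selected word multiset is conserved.
#'
#' Ties are broken by corpus frequency, then lexicographically, so the
#' construction is deterministic; `seed` is kept for interface symmetry with
#' the retrieval baselines. The output is a *synthesized* report — typically
#' ungrammatical, and not a member of the training set.
#'
#' @inheritParams baseline1_exhaustive
#' @return A `baseline_result` whose objective is the report's coco-dialect
#'   BLEU-2 against the references (the quantity the construction targets).
#' @examples
#' baseline2(list(c("a", "b"), c("a", "c")))
#' @export
baseline2 <- function(references, seed = NULL) {
  refs <- reports_from(references)
  n_target <- floor(mean(lengths(refs)) + 0.5)
  uni <- ngram_index(refs, k_max = 1)$per_k[[1]]
  words <- names(sort_by_freq(uni$occ))
  if (!length(words) || n_target == 0L) {
    return(new_baseline_result(character(0), "bleu-2 (coco)", 0, tie_ids = 1L,
                               chosen = NA_integer_, seed = seed, n_refs = length(refs)))
  }
  ge <- uni$ge
  # Step 1: word selection. gain(w) = number of references in which w still
  # has occurrences unmatched by the current multiset.
  cur <- setNames(integer(length(words)), words)
  chosen <- character(0)
  while (length(chosen) < n_target) {
    gains <- vapply(words, function(w) {
      t <- cur[[w]] + 1L
      g <- ge[[w]]
      if (t <= length(g)) g[[t]] else 0L
    }, integer(1))
    # words already ordered by (frequency desc, lexicographic), so the first
    # maximum realizes the tie rule
    w <- words[[which.max(gains)]]
    chosen <- c(chosen, w)
    cur[[w]] <- cur[[w]] + 1L
  }
  # Step 2: join along frequent 2-grams. Fragments start as the selected
  # words in selection order.
  frags <- as.list(chosen)
  bi <- ngram_index(refs, k_max = 2)$per_k[[2]]$occ
  for (bg in names(sort_by_freq(bi))) {
    ab <- strsplit(bg, " ", fixed = TRUE)[[1]]
    repeat {
      joined <- FALSE
      ends <- which(vapply(frags, function(f) f[[length(f)]] == ab[[1]], logical(1)))
      for (i in ends) {
        starts <- which(vapply(frags, function(f) f[[1]] == ab[[2]], logical(1)))
        starts <- setdiff(starts, i)
        if (length(starts)) {
          j <- starts[[1]]
          frags[[i]] <- c(frags[[i]], frags[[j]])
          frags[[j]] <- NULL
          joined <- TRUE
          break
        }
      }
      if (!joined) break
    }
  }
  # Concatenate what remains, most frequent leading word first.
  lead <- vapply(frags, `[[`, character(1), 1L)
  ord <- order(-uni$occ[lead], lead)
  tokens <- as.character(unlist(frags[ord], use.names = FALSE))
  value <- universal_bleu(tokens, refs, K = 2, dialect = "coco")
  new_baseline_result(tokens, "bleu-2 (coco)", value, tie_ids = 1L, chosen = NA_integer_,
                      seed = seed, n_refs = length(refs))
}

# Order a named count vector by count desc, then name (lexicographic).
sort_by_freq <- function(counts) {
  counts[order(-counts, names(counts))]
}

# Corpus BLEU of a single report used as candidate for every reference.
universal_bleu <- function(tokens, refs, K = 4, dialect = "coco") {
  spec <- metric_spec("bleu", K = K, dialect = dialect)
  n <- length(refs)
  matches <- vapply(seq_len(K), function(k) {
    ct <- ngram_counts(tokens, k)
    sum(vapply(refs, function(r) pair_clipped_matches(ct, ngram_counts(r, k)), integer(1)))
  }, integer(1))
  score_pooled_bleu(matches,
                    cand_grams = n * pmax(0L, length(tokens) - seq_len(K) + 1L),
                    n_C = n * length(tokens), n_R = sum(lengths(refs)), spec = spec)
}
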