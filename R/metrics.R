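#' Describe a corpus-level metric
#'
#' A metric spec bundles a metric name with its tuning parameters so the same
#' configuration can be reused across evaluation, stratification, baselines
#' and the bootstrap test. Shorthand strings are accepted everywhere a spec
#' is: `"bleu-1"` .. `"bleu-4"` (coco dialect), `"rouge_l"`, `"meteor"`,
#' `"cider"`, `"cider-d"`, `"accuracy"`.
#'
#' Two BLEU dialects are provided. `"coco"` (default) is the conventional
#' corpus BLEU: per-order precisions with total candidate k-grams in the
#' denominator, combined by geometric mean under the brevity penalty — the
#' behaviour of the widely used COCO caption evaluation toolkit. `"paper"`
#' is the literal summed form `BP * sum_k precision_k` with every precision
#' normalized by the total candidate *token* count; it is exposed because
#' some radiology-report evaluations print BLEU that way, and the two
#' dialects rank systems differently.
#'
#' For CIDEr, `variant = "d"` (default) adds the Gaussian report-length
#' penalty `exp(-(|c|-|r|)^2 / (2 sigma^2))`, clips candidate gram weights at
#' the reference's, and scales by 10, giving per-pair scores in \[0, 10\];
#' `variant = "plain"` is the plain average tf-idf cosine in \[0, 1\].
#' `length_penalty = "linear"` replaces the squared length difference with a
#' signed linear one for comparison with implementations that omit the
#' square; the default is the standard squared form.
#'
#' @param metric One of `"bleu"`, `"rouge_l"`, `"meteor"`, `"cider"`,
#'   `"accuracy"`, or a shorthand string such as `"bleu-2"` or `"cider-d"`.
#' @param K Maximum gram order for BLEU / CIDEr (default 4).
#' @param dialect BLEU dialect, `"coco"` or `"paper"`.
#' @param beta ROUGE-L recall weight (default 1.2).
#' @param variant CIDEr variant, `"d"` or `"plain"`.
#' @param sigma CIDEr-D length-penalty scale in tokens (default 6).
#' @param length_penalty CIDEr-D penalty form, `"squared"` or `"linear"`.
#' @param index Optional [ngram_index()] supplying CIDEr idf weights (e.g. a
#'   training corpus); by default the index is built over the reference side
#'   of whatever corpus is being scored.
#' @param lexicon Labeling rules for `"accuracy"`; default
#'   [default_lexicon()].
#' @param average `"micro"` (over label cells) or `"macro"` (over
#'   categories) for `"accuracy"`.
#' @return An object of class `metric_spec`.
#' @examples
#' metric_spec("bleu", K = 2, dialect = "paper")
#' as_metric_spec("cider-d")
#' @export
metric_spec <- function(metric = c("bleu", "rouge_l", "meteor", "cider", "accuracy"),
                        K = 4, dialect = c("coco", "paper"), beta = 1.2,
                        variant = c("d", "plain"), sigma = 6,
                        length_penalty = c("squared", "linear"),
                        index = NULL, lexicon = NULL,
                        average = c("micro", "macro")) {
  metric <- match.arg(metric)
  dialect <- match.arg(dialect)
  variant <- match.arg(variant)
  length_penalty <- match.arg(length_penalty)
  average <- match.arg(average)
  K <- as.integer(K)
  if (is.na(K) || K < 1) abort("`K` must be an integer >= 1.")
  if (beta <= 0) abort("`beta` must be positive.")
  if (sigma <= 0) abort("`sigma` must be positive.")
  label <- switch(metric,
    bleu = sprintf("bleu-%d", K),
    rouge_l = "rouge_l",
    meteor = "meteor",
    cider = if (variant == "d") "cider-d" else sprintf("cider-%d", K),
    accuracy = "accuracy"
  )
  structure(
    list(metric = metric, label = label, K = K, dialect = dialect, beta = beta,
         variant = variant, sigma = sigma, length_penalty = length_penalty,
         index = index, lexicon = lexicon, average = average),
    class = "metric_spec"
  )
}

#' @rdname metric_spec
#' @param x A `metric_spec` or shorthand string.
#' @param ... Extra arguments passed to [metric_spec()] when parsing a
#'   shorthand string.
#' @export
as_metric_spec <- function(x, ...) {
  if (inherits(x, "metric_spec")) return(x)
  if (!is.character(x) || length(x) != 1) {
    abort("Metrics must be metric_spec objects or shorthand strings.")
  }
  key <- tolower(gsub("[ _]", "-", trimws(x)))
  if (grepl("^bleu-?[0-9]$", key)) {
    return(metric_spec("bleu", K = as.integer(sub("^bleu-?", "", key)), ...))
  }
  switch(key,
    "bleu" = metric_spec("bleu", ...),
    "rouge" = , "rouge-l" = metric_spec("rouge_l", ...),
    "meteor" = metric_spec("meteor", ...),
    "cider" = metric_spec("cider", variant = "plain", ...),
    "cider-d" = , "ciderd" = metric_spec("cider", variant = "d", ...),
    "accuracy" = , "label-accuracy" = metric_spec("accuracy", ...),
    abort(sprintf("Unknown metric: \"%s\".", x))
  )
}

#' @export
print.metric_spec <- function(x, ...) {
  extra <- switch(x$metric,
    bleu = sprintf("dialect = %s", x$dialect),
    rouge_l = sprintf("beta = %g", x$beta),
    cider = sprintf("K = %d, sigma = %g", x$K, x$sigma),
    "")
  cat(sprintf("<metric_spec> %s%s\n", x$label, if (nzchar(extra)) paste0(" (", extra, ")") else ""))
  invisible(x)
}

#' Brevity penalty
#'
#' BLEU's multiplicative penalty for candidate corpora shorter in total than
#' their references: `min(1, exp(1 - n_R / n_C))`, equal to 1 whenever the
#' candidates are at least as long. The degenerate case `n_C = 0` is defined
#' as 0 so that empty candidate corpora score 0.
#'
#' @param n_C Total candidate tokens.
#' @param n_R Total reference tokens.
#' @return A number in \[0, 1\].
#' @examples
#' brevity_penalty(2, 4) # exp(-1)
#' @export
brevity_penalty <- function(n_C, n_R) {
  if (n_C < 0 || n_R < 0) abort("Token totals must be nonnegative.")
  if (n_C == 0) return(0)
  min(1, exp(1 - n_R / n_C))
}

## ---- per-pair computations -------------------------------------------------

# Clipped k-gram matches between one candidate and one reference.
pair_clipped_matches <- function(cand_counts, ref_counts) {
  common <- intersect(names(cand_counts), names(ref_counts))
  if (!length(common)) return(0L)
  sum(pmin(cand_counts[common], ref_counts[common]))
}

# Longest common subsequence length between two token vectors (row-rolling
# dynamic programme).
lcs_length <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  u <- unique(c(a, b))
  a <- match(a, u)
  b <- match(b, u)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    ai <- a[[i]]
    for (j in seq_len(nb)) {
      cur[[j + 1L]] <- if (ai == b[[j]]) prev[[j]] + 1L else max(cur[[j]], prev[[j + 1L]])
    }
    prev <- cur
  }
  prev[[nb + 1L]]
}

pair_rouge_l <- function(cand, ref, beta = 1.2) {
  l <- lcs_length(cand, ref)
  if (l == 0L) return(0)
  p <- l / length(cand)
  r <- l / length(ref)
  ((1 + beta^2) * p * r) / (beta^2 * p + r)
}

# Monotone-in-neither greedy alignment of exact unigram matches that takes
# the longest common contiguous block first; total matched positions equals
# the clipped unigram match count, and chunks are maximal runs contiguous in
# both reports.
meteor_alignment <- function(cand, ref) {
  nc <- length(cand)
  nr <- length(ref)
  used_c <- logical(nc)
  used_r <- logical(nr)
  blocks <- list()
  repeat {
    best_len <- 0L
    best <- NULL
    for (i in seq_len(nc)) {
      if (used_c[[i]]) next
      for (j in seq_len(nr)) {
        if (used_r[[j]] || cand[[i]] != ref[[j]]) next
        l <- 0L
        while (i + l <= nc && j + l <= nr && !used_c[[i + l]] && !used_r[[j + l]] &&
               cand[[i + l]] == ref[[j + l]]) {
          l <- l + 1L
        }
        if (l > best_len) {
          best_len <- l
          best <- c(i, j)
        }
      }
    }
    if (best_len == 0L) break
    span <- seq_len(best_len) - 1L
    used_c[best[[1]] + span] <- TRUE
    used_r[best[[2]] + span] <- TRUE
    blocks[[length(blocks) + 1L]] <- cbind(best[[1]] + span, best[[2]] + span)
  }
  if (!length(blocks)) return(matrix(integer(0), 0, 2))
  al <- do.call(rbind, blocks)
  al[order(al[, 1]), , drop = FALSE]
}

pair_meteor <- function(cand, ref) {
  if (!length(cand) || !length(ref)) return(0)
  al <- meteor_alignment(cand, ref)
  m <- nrow(al)
  if (m == 0L) return(0)
  # chunks: maximal runs contiguous in both candidate and reference
  if (m == 1L) {
    chunks <- 1L
  } else {
    breaks <- diff(al[, 1]) != 1L | diff(al[, 2]) != 1L
    chunks <- 1L + sum(breaks)
  }
  p <- m / length(cand)
  r <- m / length(ref)
  fmean <- 10 * p * r / (9 * p + r)
  cp <- chunks / m
  (1 - 0.5 * cp^3) * fmean
}

cider_length_penalty <- function(len_c, len_r, sigma, form = "squared") {
  d <- len_c - len_r
  if (form == "squared") exp(-d^2 / (2 * sigma^2)) else exp(-d / (2 * sigma^2))
}

pair_cider <- function(cand, ref, spec, index) {
  total <- 0
  for (k in seq_len(spec$K)) {
    gc <- tfidf_vector(cand, k, index)
    gr <- tfidf_vector(ref, k, index)
    ngc <- sqrt(sum(gc^2))
    ngr <- sqrt(sum(gr^2))
    if (ngc == 0 || ngr == 0) next
    common <- intersect(names(gc), names(gr))
    if (!length(common)) next
    if (spec$variant == "plain") {
      total <- total + sum(gc[common] * gr[common]) / (ngc * ngr)
    } else {
      num <- sum(pmin(gc[common], gr[common]) * gr[common])
      pen <- cider_length_penalty(length(cand), length(ref), spec$sigma, spec$length_penalty)
      total <- total + 10 * pen * num / (ngc * ngr)
    }
  }
  total / spec$K
}

## ---- sufficient statistics + aggregation ----------------------------------

# Per-record sufficient statistics for a metric, together with an aggregator
# that recomputes the corpus-level score for an arbitrary multiset of record
# indices. Pooled quantities (brevity penalty, clipped-count precisions) are
# recomputed from the pooled sums, so aggregating over a resampled index
# vector is identical to rescoring the materialized resampled corpus.
metric_stats <- function(spec, corpus) {
  spec <- as_metric_spec(spec)
  check_corpus(corpus, require_candidate = TRUE)
  cands <- corpus$candidate
  refs <- corpus$reference
  n <- nrow(corpus)
  if (spec$metric == "bleu") {
    K <- spec$K
    mat <- matrix(0, nrow = n, ncol = 2 + 2 * K)
    colnames(mat) <- c("len_c", "len_r", paste0("match_", seq_len(K)), paste0("cand_", seq_len(K)))
    for (i in seq_len(n)) {
      ci <- cands[[i]]
      ri <- refs[[i]]
      mat[i, "len_c"] <- length(ci)
      mat[i, "len_r"] <- length(ri)
      for (k in seq_len(K)) {
        cc <- ngram_counts(ci, k)
        mat[i, 2 + k] <- pair_clipped_matches(cc, ngram_counts(ri, k))
        mat[i, 2 + K + k] <- max(0L, length(ci) - k + 1L)
      }
    }
    dialect <- spec$dialect
    aggregate <- function(idx) {
      s <- colSums(mat[idx, , drop = FALSE])
      n_C <- s[["len_c"]]
      if (n_C == 0) return(0)
      bp <- brevity_penalty(n_C, s[["len_r"]])
      matches <- s[2 + seq_len(K)]
      if (dialect == "paper") {
        bp * sum(matches) / n_C
      } else {
        denom <- s[2 + K + seq_len(K)]
        if (any(denom == 0) || any(matches == 0)) return(0)
        bp * exp(mean(log(matches / denom)))
      }
    }
    structure(list(spec = spec, n = n, per_item = NULL, data = mat, aggregate = aggregate),
              class = "metric_stats")
  } else if (spec$metric == "accuracy") {
    lex <- spec$lexicon %||% default_lexicon()
    ref_lab <- label_matrix_from_reports(refs, lex)
    cand_lab <- label_matrix_from_reports(cands, lex)
    agree <- cand_lab == ref_lab
    per_item <- rowMeans(agree)
    aggregate <- function(idx) mean(agree[idx, , drop = FALSE])
    structure(list(spec = spec, n = n, per_item = per_item, data = agree, aggregate = aggregate),
              class = "metric_stats")
  } else {
    per_item <- switch(spec$metric,
      rouge_l = vapply(seq_len(n), function(i) {
        pair_rouge_l(cands[[i]], refs[[i]], spec$beta)
      }, numeric(1)),
      meteor = vapply(seq_len(n), function(i) pair_meteor(cands[[i]], refs[[i]]), numeric(1)),
      cider = {
        index <- spec$index %||% ngram_index(refs, k_max = spec$K)
        vapply(seq_len(n), function(i) pair_cider(cands[[i]], refs[[i]], spec, index), numeric(1))
      }
    )
    aggregate <- function(idx) mean(per_item[idx])
    structure(list(spec = spec, n = n, per_item = per_item, data = per_item, aggregate = aggregate),
              class = "metric_stats")
  }
}

new_metric_result <- function(spec, score, per_item, corpus) {
  structure(
    list(
      metric = spec$label,
      dialect = if (spec$metric == "bleu") spec$dialect else NA_character_,
      score = as.numeric(score),
      per_item = if (!is.null(per_item)) tibble(id = corpus$id, score = as.numeric(per_item)),
      n = nrow(corpus),
      spec = spec
    ),
    class = "metric_result"
  )
}

#' Score a corpus under one metric configuration
#'
#' @param corpus A corpus tibble with candidates.
#' @param spec A [metric_spec()] or shorthand string.
#' @return A `metric_result`: corpus score plus, for the pair-averaged
#'   metrics, per-record scores. Use [tidy()] for the per-record table and
#'   [glance()] for a one-row summary.
#' @examples
#' corpus <- report_corpus(c("the heart is normal"), c("the heart is normal"))
#' metric_score(corpus, "rouge_l")
#' @export
metric_score <- function(corpus, spec) {
  spec <- as_metric_spec(spec)
  st <- metric_stats(spec, corpus)
  new_metric_result(spec, st$aggregate(seq_len(st$n)), st$per_item, corpus)
}

#' @export
print.metric_result <- function(x, ...) {
  dial <- if (!is.na(x$dialect)) sprintf(" [%s]", x$dialect) else ""
  cat(sprintf("<metric_result> %s%s = %.6f over %d report pairs\n", x$metric, dial, x$score, x$n))
  invisible(x)
}

#' @method tidy metric_result
#' @export
tidy.metric_result <- function(x, ...) {
  x$per_item %||% tibble(id = character(0), score = numeric(0))
}

#' @method glance metric_result
#' @export
glance.metric_result <- function(x, ...) {
  tibble(metric = x$metric, dialect = x$dialect, score = x$score, n = x$n)
}

#' @method autoplot metric_result
#' @export
autoplot.metric_result <- function(object, bins = 30, ...) {
  if (is.null(object$per_item)) {
    abort("This metric has no per-report scores to plot (corpus-pooled metric).")
  }
  ggplot2::ggplot(object$per_item, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$score, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("per-report %s", object$metric),
      y = "reports",
      title = sprintf("%s = %.3f (corpus mean, n = %d)", object$metric, object$score, object$n)
    )
}

## ---- exported metric wrappers ----------------------------------------------

#' Corpus BLEU
#'
#' @inheritParams metric_score
#' @param K Maximum gram order.
#' @param dialect `"coco"` (geometric-mean corpus BLEU, default) or
#'   `"paper"` (summed precisions over the total candidate token count); see
#'   [metric_spec()] for the distinction.
#' @return A `metric_result`.
#' @export
bleu <- function(corpus, K = 4, dialect = c("coco", "paper")) {
  metric_score(corpus, metric_spec("bleu", K = K, dialect = match.arg(dialect)))
}

#' Corpus ROUGE-L
#'
#' Longest-common-subsequence F-score per report pair (recall weighted by
#' `beta`), averaged over the corpus. Pairs with no common subsequence score
#' 0.
#'
#' @inheritParams metric_score
#' @param beta Recall weight (default 1.2).
#' @return A `metric_result`.
#' @export
rouge_l <- function(corpus, beta = 1.2) {
  metric_score(corpus, metric_spec("rouge_l", beta = beta))
}

#' Corpus METEOR (exact-match form)
#'
#' Harmonic-mean unigram F-score weighted 9:1 towards recall, with the
#' fragmentation penalty `1 - 0.5 * (chunks / matches)^3`; matching is exact
#' surface form (no stemming or synonymy) and chunks are minimized by a
#' longest-run greedy alignment. Averaged over report pairs.
#'
#' @inheritParams metric_score
#' @return A `metric_result`.
#' @export
meteor <- function(corpus) {
  metric_score(corpus, metric_spec("meteor"))
}

#' Corpus CIDEr / CIDEr-D
#'
#' Average tf-idf cosine agreement over gram orders `1..K`. Grams that occur
#' in every indexed reference have idf 0 and contribute nothing — which is
#' why boilerplate sentences shared by all reports cannot raise a CIDEr
#' score.
#'
#' @inheritParams metric_score
#' @param K Maximum gram order (default 4).
#' @param variant `"d"` (length penalty, clipping, x10 scale; default) or
#'   `"plain"`.
#' @param sigma Length-penalty scale in tokens (default 6).
#' @param index Optional [ngram_index()] giving idf weights; defaults to an
#'   index over this corpus's references.
#' @return A `metric_result`.
#' @export
cider <- function(corpus, K = 4, variant = c("d", "plain"), sigma = 6, index = NULL) {
  metric_score(corpus, metric_spec("cider", K = K, variant = match.arg(variant),
                                   sigma = sigma, index = index))
}

#' Evaluate several metrics on one corpus
#'
#' Runs each configured metric and binds the one-row summaries. CIDEr
#' configurations without an explicit index share a single index built over
#' this corpus's references.
#'
#' @inheritParams metric_score
#' @param metrics List (or character vector of shorthands) of metric
#'   configurations. Default: BLEU-1..4 (coco), ROUGE-L, METEOR, CIDEr-D.
#' @param lexicon Lexicon used by any `"accuracy"` entry.
#' @return A tibble with one row per metric: `metric`, `dialect`, `score`,
#'   `n`.
#' @examples
#' corpus <- report_corpus(c("the heart is normal"), c("the heart is enlarged"))
#' evaluate_metrics(corpus, c("bleu-1", "rouge_l"))
#' @export
evaluate_metrics <- function(corpus,
                             metrics = c("bleu-1", "bleu-2", "bleu-3", "bleu-4",
                                         "rouge_l", "meteor", "cider-d"),
                             lexicon = NULL) {
  if (length(metrics) == 0) {
    return(tibble(metric = character(0), dialect = character(0),
                  score = numeric(0), n = integer(0)))
  }
  specs <- lapply(as.list(metrics), as_metric_spec)
  shared_index <- NULL
  needs_index <- vapply(specs, function(s) s$metric == "cider" && is.null(s$index), logical(1))
  if (any(needs_index)) {
    kmax <- max(vapply(specs[needs_index], `[[`, integer(1), "K"))
    shared_index <- ngram_index(corpus, k_max = kmax)
  }
  rows <- lapply(specs, function(s) {
    if (s$metric == "cider" && is.null(s$index)) s$index <- shared_index
    if (s$metric == "accuracy" && is.null(s$lexicon)) s$lexicon <- lexicon
    glance(metric_score(corpus, s))
  })
  dplyr::bind_rows(rows)
}
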