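#' Percentile confidence interval
#'
#' Empirical `alpha/2` and `1 - alpha/2` quantiles with linear interpolation
#' (the default sample-quantile definition).
#'
#' @param values Nonempty numeric vector.
#' @param alpha Two-sided error level in (0, 1); default 0.05 for a 95%
#'   interval.
#' @return A named numeric vector `c(low, high)`.
#' @examples
#' percentile_ci(1:100, 0.05)
#' @export
percentile_ci <- function(values, alpha = 0.05) {
  if (!length(values)) abort("`values` must be nonempty.")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  q <- quantile(values, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(low = q[[1]], high = q[[2]])
}

#' Paired bootstrap test for a difference in corpus scores
#'
#' Compares two candidate-report systems `A` and `B` over the same reference
#' set using the score difference `delta = s(A) - s(B)` as the test
#' statistic. Test sets are resampled with replacement at the record level
#' (reference plus both candidates move together), the metric is recomputed
#' on each resampled set, and the null distribution is the bootstrap
#' distribution of `delta` recentered to mean zero (a shape-preserving mean
#' shift). The two-sided p-value uses add-one smoothing,
#' `p = (1 + #\{|delta_b - mean| >= |delta_obs|\}) / (B + 1)`, so it is
#' never exactly zero.
#'
#' Corpus-pooled statistics (brevity penalty, pooled clipped counts) are
#' recomputed for every replicate from per-record sufficient statistics,
#' which is identical to rescoring the materialized resampled corpus.
#'
#' @param corpus A corpus tibble providing the references (its own
#'   `candidate` column, if any, is ignored).
#' @param candidates_a,candidates_b The two systems' candidate reports: raw
#'   character vectors, lists of token vectors, or corpus tibbles with a
#'   candidate column (ids must then match `corpus`).
#' @param metric A [metric_spec()] or shorthand string.
#' @param B Number of bootstrap replicates (default 1000).
#' @param alpha Level for the percentile intervals (default 0.05).
#' @param seed Integer seed (optional). With the same seed, swapping
#'   `candidates_a` and `candidates_b` negates the observed delta and leaves
#'   the p-value unchanged.
#' @return A `bootstrap_outcome` with the observed delta, replicate
#'   summaries, percentile intervals for the delta and for each system's
#'   score, and the p-value. [tidy()] returns the replicate table,
#'   [glance()] a one-row summary, [autoplot()] the replicate score
#'   distributions with their confidence bands.
#' @export
bootstrap_compare <- function(corpus, candidates_a, candidates_b, metric,
                              B = 1000, alpha = 0.05, seed = NULL) {
  check_corpus(corpus)
  B <- as.integer(B)
  if (is.na(B) || B < 1) abort("`B` must be an integer >= 1.")
  spec <- as_metric_spec(metric)
  n <- nrow(corpus)
  attach_candidates <- function(cands, which) {
    if (is.data.frame(cands)) {
      check_corpus(cands, require_candidate = TRUE)
      if (nrow(cands) != n || !identical(cands$id, corpus$id)) {
        abort(sprintf("`candidates_%s` is not aligned with the corpus records.", which))
      }
      cands <- cands$candidate
    } else {
      cands <- as_report_list(cands, what = sprintf("candidates_%s", which))
      if (length(cands) != n) {
        abort(sprintf("`candidates_%s` must have one report per corpus record.", which))
      }
    }
    out <- corpus[c("id", "reference")]
    out$candidate <- cands
    out
  }
  corpus_a <- attach_candidates(candidates_a, "a")
  corpus_b <- attach_candidates(candidates_b, "b")
  # one shared idf index so both systems are scored on the same scale
  if (spec$metric == "cider" && is.null(spec$index)) {
    spec$index <- ngram_index(corpus, k_max = spec$K)
  }
  stats_a <- metric_stats(spec, corpus_a)
  stats_b <- metric_stats(spec, corpus_b)
  all_idx <- seq_len(n)
  score_a <- stats_a$aggregate(all_idx)
  score_b <- stats_b$aggregate(all_idx)
  delta_obs <- score_a - score_b
  idx <- with_seed_if(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = n))
  rep_a <- numeric(B)
  rep_b <- numeric(B)
  for (b in seq_len(B)) {
    rep_a[[b]] <- stats_a$aggregate(idx[, b])
    rep_b[[b]] <- stats_b$aggregate(idx[, b])
  }
  deltas <- rep_a - rep_b
  centered <- abs(deltas - mean(deltas))
  p_value <- (1 + sum(centered >= abs(delta_obs))) / (B + 1)
  ci <- percentile_ci(deltas, alpha)
  structure(
    list(
      metric = spec$label,
      delta_observed = delta_obs,
      score_a = score_a, score_b = score_b,
      B = B, alpha = alpha, seed = seed, n = n,
      replicates = tibble(delta = deltas, score_a = rep_a, score_b = rep_b),
      delta_mean = mean(deltas), delta_sd = sd(deltas),
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      ci_a = percentile_ci(rep_a, alpha),
      ci_b = percentile_ci(rep_b, alpha),
      p_value = p_value
    ),
    class = "bootstrap_outcome"
  )
}

#' @export
print.bootstrap_outcome <- function(x, ...) {
  cat(sprintf("<bootstrap_outcome> %s: delta = %.6f (A = %.6f, B = %.6f)\n",
              x$metric, x$delta_observed, x$score_a, x$score_b))
  cat(sprintf("  %d replicates over %d records; %g%% CI [%.6f, %.6f]; p = %.4g\n",
              x$B, x$n, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @method tidy bootstrap_outcome
#' @export
tidy.bootstrap_outcome <- function(x, ...) {
  x$replicates
}

#' @method glance bootstrap_outcome
#' @export
glance.bootstrap_outcome <- function(x, ...) {
  tibble(
    metric = x$metric, delta_observed = x$delta_observed,
    score_a = x$score_a, score_b = x$score_b,
    delta_mean = x$delta_mean, delta_sd = x$delta_sd,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, B = x$B, alpha = x$alpha, n = x$n
  )
}

#' @method autoplot bootstrap_outcome
#' @export
autoplot.bootstrap_outcome <- function(object, bins = 40, ...) {
  long <- tidyr::pivot_longer(object$replicates, c("score_a", "score_b"),
                              names_to = "system", values_to = "score")
  bands <- tibble(
    system = c("score_a", "score_b"),
    low = c(object$ci_a[["low"]], object$ci_b[["low"]]),
    high = c(object$ci_a[["high"]], object$ci_b[["high"]])
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, fill = .data$system)) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$low, xmax = .data$high, ymin = -Inf, ymax = Inf),
      fill = "lightyellow", alpha = 0.6, inherit.aes = FALSE
    ) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~ .data$system, ncol = 1) +
    ggplot2::labs(
      x = sprintf("bootstrap %s", object$metric), y = "replicates",
      title = sprintf("delta = %.4f, p = %.4g (B = %d)",
                      object$delta_observed, object$p_value, object$B)
    ) +
    ggplot2::theme(legend.position = "none")
}
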