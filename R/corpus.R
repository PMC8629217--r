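#' Build a parallel report corpus
#'
#' A corpus is an ordinary tibble with one row per record: an `id`, a
#' `reference` report (list-column of token vectors), and optionally a
#' `candidate` report and a stratum `tag` (e.g. `"normal"` / `"abnormal"`).
#' Raw text inputs are cleaned with [preprocess_text()]; pre-tokenized lists
#' are validated. All evaluation functions in the package take this tibble
#' first, so calls chain with the pipe.
#'
#' @param reference Character vector of raw reference texts, or a list of
#'   token vectors.
#' @param candidate Optional candidate reports, same forms as `reference`.
#' @param id Optional character ids; defaults to `"r1"`, `"r2"`, ... Ids must
#'   be unique.
#' @param tag Optional character stratum labels.
#' @param drop_placeholders Passed to [preprocess_text()].
#' @return A tibble with columns `id`, `reference`, and when supplied
#'   `candidate` and `tag`.
#' @examples
#' report_corpus(
#'   reference = c("The heart is normal.", "There is a pleural effusion."),
#'   candidate = c("Heart is normal.", "No pleural effusion.")
#' )
#' @export
report_corpus <- function(reference, candidate = NULL, id = NULL, tag = NULL,
                          drop_placeholders = TRUE) {
  refs <- as_report_list(reference, drop_placeholders, what = "reference")
  if (is.null(refs) || length(refs) == 0) abort("A corpus needs at least one reference report.")
  n <- length(refs)
  id <- as.character(id %||% paste0("r", seq_len(n)))
  if (length(id) != n) abort("`id` must have one entry per reference.")
  if (anyDuplicated(id)) {
    abort(sprintf("Duplicate id(s): %s.", paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  out <- tibble(id = id, reference = refs)
  if (!is.null(candidate)) {
    cands <- as_report_list(candidate, drop_placeholders, what = "candidate")
    if (length(cands) != n) abort("`candidate` must have one entry per reference.")
    out$candidate <- cands
  }
  if (!is.null(tag)) {
    if (length(tag) != n) abort("`tag` must have one entry per reference.")
    out$tag <- as.character(tag)
  }
  out
}

# Internal corpus validation used by every evaluation entry point.
check_corpus <- function(corpus, require_candidate = FALSE, require_tag = FALSE) {
  if (!is.data.frame(corpus) || !all(c("id", "reference") %in% names(corpus))) {
    abort("`corpus` must be a data frame with `id` and `reference` columns (see report_corpus()).")
  }
  if (nrow(corpus) < 1) abort("`corpus` has no records.")
  if (anyDuplicated(corpus$id)) abort("Corpus ids must be unique.")
  if (require_candidate) {
    if (!"candidate" %in% names(corpus)) abort("This operation needs a `candidate` column.")
    missing <- vapply(corpus$candidate, is.null, logical(1))
    if (any(missing)) {
      abort(sprintf("Record(s) without a candidate report: %s.",
                    paste(corpus$id[missing], collapse = ", ")))
    }
  }
  if (require_tag) {
    if (!"tag" %in% names(corpus) || anyNA(corpus$tag)) {
      bad <- if (!"tag" %in% names(corpus)) corpus$id else corpus$id[is.na(corpus$tag)]
      abort(sprintf("Record(s) without a stratum tag: %s.", paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(corpus)
}

corpus_side <- function(corpus, side = c("reference", "candidate")) {
  side <- match.arg(side)
  check_corpus(corpus, require_candidate = side == "candidate")
  corpus[[side]]
}

#' Read a parallel corpus from disk
#'
#' Three plain-text dialects are supported:
#' * `jsonl` — one JSON object per line with keys `id`, `reference`, and
#'   optionally `candidate` and `tag`;
#' * `text_pair` — one report per line in `path` (references) and, optionally,
#'   a parallel file of candidates (`candidate_path`), paired by line number;
#' * `csv` — columns `id`, `reference` and optionally `candidate`, `tag`.
#'
#' Report texts are cleaned with [preprocess_text()] on load, so a write /
#' read round trip reproduces the same token sequences.
#'
#' @param path Input file.
#' @param format One of `"jsonl"`, `"text_pair"`, `"csv"`.
#' @param candidate_path Second file for `format = "text_pair"`.
#' @param drop_placeholders Passed to [preprocess_text()].
#' @return A corpus tibble (see [report_corpus()]).
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("jsonl", "text_pair", "csv"),
                        candidate_path = NULL, drop_placeholders = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) abort(sprintf("No records in %s.", path))
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) abort(sprintf("Malformed JSON on line %d of %s.", i, path)))
      if (is.null(obj$reference)) {
        abort(sprintf("Record on line %d of %s lacks a \"reference\" field.", i, path))
      }
      obj
    })
    grab <- function(field) {
      vals <- lapply(recs, `[[`, field)
      if (all(vapply(vals, is.null, logical(1)))) NULL else
        vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v), character(1))
    }
    report_corpus(
      reference = vapply(recs, function(r) as.character(r$reference), character(1)),
      candidate = grab("candidate"),
      id = grab("id") %||% paste0("r", seq_along(recs)),
      tag = grab("tag"),
      drop_placeholders = drop_placeholders
    )
  } else if (format == "text_pair") {
    refs <- readLines(path, warn = FALSE, encoding = "UTF-8")
    if (!length(refs)) abort(sprintf("No records in %s.", path))
    cands <- NULL
    if (!is.null(candidate_path)) {
      cands <- readLines(candidate_path, warn = FALSE, encoding = "UTF-8")
      if (length(cands) != length(refs)) {
        abort("Reference and candidate files have different numbers of lines.")
      }
    }
    report_corpus(refs, cands, drop_placeholders = drop_placeholders)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"reference" %in% names(df)) abort(sprintf("%s lacks a `reference` column.", path))
    if (anyNA(df$reference)) {
      abort(sprintf("Missing reference in row(s): %s.",
                    paste(which(is.na(df$reference)), collapse = ", ")))
    }
    report_corpus(
      reference = as.character(df$reference),
      candidate = if ("candidate" %in% names(df)) as.character(df$candidate),
      id = if ("id" %in% names(df)) as.character(df$id),
      tag = if ("tag" %in% names(df)) as.character(df$tag),
      drop_placeholders = drop_placeholders
    )
  }
}

#' Write a parallel corpus to disk
#'
#' Token sequences are stored as space-joined text; because cleaning is
#' idempotent, reloading reproduces the corpus exactly.
#'
#' @param corpus A corpus tibble.
#' @param path Output file (references file for `text_pair`).
#' @param format One of `"jsonl"`, `"text_pair"`, `"csv"`.
#' @param candidate_path Candidate file for `format = "text_pair"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "text_pair", "csv"),
                         candidate_path = NULL) {
  format <- match.arg(format)
  check_corpus(corpus)
  join <- function(col) vapply(col, paste, character(1), collapse = " ")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(id = corpus$id[[i]], reference = paste(corpus$reference[[i]], collapse = " "))
      if ("candidate" %in% names(corpus) && !is.null(corpus$candidate[[i]])) {
        rec$candidate <- paste(corpus$candidate[[i]], collapse = " ")
      }
      if ("tag" %in% names(corpus) && !is.na(corpus$tag[[i]])) rec$tag <- corpus$tag[[i]]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else if (format == "text_pair") {
    writeLines(join(corpus$reference), path)
    if (!is.null(candidate_path)) {
      check_corpus(corpus, require_candidate = TRUE)
      writeLines(join(corpus$candidate), candidate_path)
    }
  } else {
    df <- tibble(id = corpus$id, reference = join(corpus$reference))
    if ("candidate" %in% names(corpus)) df$candidate <- join(corpus$candidate)
    if ("tag" %in% names(corpus)) df$tag <- corpus$tag
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Summarize one side of a corpus
#'
#' Token-level bookkeeping for either the reference or the candidate side:
#' the number of reports, total token count, mean report length (the `n` used
#' by the greedy report synthesizer, see [baseline2()]) and vocabulary size.
#'
#' @param corpus A corpus tibble.
#' @param side `"reference"` (default) or `"candidate"`.
#' @return A one-row tibble with `n_reports`, `total_tokens`,
#'   `mean_report_length`, `vocabulary_size`.
#' @examples
#' corpus_summary(report_corpus(c("the heart is normal", "lungs are clear")))
#' @export
corpus_summary <- function(corpus, side = c("reference", "candidate")) {
  side <- match.arg(side)
  reports <- corpus_side(corpus, side)
  lens <- lengths(reports)
  tibble(
    side = side,
    n_reports = length(reports),
    total_tokens = sum(lens),
    mean_report_length = mean(lens),
    vocabulary_size = length(unique(unlist(reports, use.names = FALSE)))
  )
}
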