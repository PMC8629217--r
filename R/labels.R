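#' Finding categories used by the default labeler
#'
#' The 14 chest X-ray finding categories popularized by the CheXpert
#' labeling scheme, in their conventional order, as snake_case names.
#'
#' @return A character vector of 14 category names.
#' @export
chexpert_categories <- function() {
  c("no_finding", "enlarged_cardiomediastinum", "cardiomegaly", "lung_opacity",
    "lung_lesion", "edema", "consolidation", "pneumonia", "atelectasis",
    "pneumothorax", "pleural_effusion", "pleural_other", "fracture",
    "support_devices")
}

#' Construct a labeling lexicon
#'
#' The labeler in this package is a deliberately simple rule engine standing
#' in for full clinical label extractors: a category is positive when one of
#' its mention phrases occurs in a report *without* a negation cue in the
#' token window immediately preceding the phrase, and negative otherwise
#' (including when the category is never mentioned). Labels are binary;
#' uncertainty is not modelled.
#'
#' @param phrases Named list (one entry per category) of mention phrases;
#'   each phrase is a character vector of tokens or a single space-separated
#'   string. Every category needs at least one phrase.
#' @param cues Character vector of negation cue tokens.
#' @param window Number of tokens preceding a phrase in which a cue negates
#'   it (default 3, wide enough for "no ...", "without ...", "free of ...").
#' @return An object of class `report_lexicon`.
#' @seealso [default_lexicon()], [extract_labels()]
#' @export
lexicon <- function(phrases, cues = c("no", "not", "without", "free", "absent"),
                    window = 3) {
  if (!is.list(phrases) || is.null(names(phrases)) || any(!nzchar(names(phrases)))) {
    abort("`phrases` must be a named list with one entry per category.")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1) abort("`window` must be an integer >= 1.")
  cues <- validate_report(tolower(cues), what = "negation cue set")
  phrases <- lapply(phrases, function(ps) {
    ps <- lapply(as.list(ps), function(p) {
      toks <- if (length(p) == 1) strsplit(p, "\\s+")[[1]] else as.character(p)
      validate_report(tolower(toks), what = "mention phrase")
    })
    if (!length(ps) || any(lengths(ps) == 0)) abort("Every category needs >= 1 nonempty phrase.")
    ps
  })
  structure(list(categories = names(phrases), phrases = phrases,
                 cues = cues, window = window),
            class = "report_lexicon")
}

#' @export
print.report_lexicon <- function(x, ...) {
  cat(sprintf("<report_lexicon> %d categories, %d cues, window = %d\n",
              length(x$categories), length(x$cues), x$window))
  invisible(x)
}

#' The bundled 14-category lexicon
#'
#' Mention phrases and negation cues for the 14 standard chest X-ray finding
#' categories, stored as YAML under `inst/extdata/lexicon.yaml`. This is a
#' compact rule set written for this package — adequate for the synthetic
#' corpora generated here, not a reproduction of any external clinical
#' labeler.
#'
#' @return A `report_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml", package = "reporteval"))
}

#' @rdname default_lexicon
#' @param path A YAML file with keys `phrases` (category -> list of phrase
#'   strings), and optionally `cues` and `window`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  spec <- yaml::read_yaml(path)
  if (is.null(spec$phrases)) abort("Lexicon YAML needs a `phrases` mapping.")
  args <- list(phrases = spec$phrases)
  if (!is.null(spec$cues)) args$cues <- unlist(spec$cues)
  if (!is.null(spec$window)) args$window <- spec$window
  do.call(lexicon, args)
}

# Start positions at which `phrase` occurs in `tokens`.
phrase_positions <- function(tokens, phrase) {
  lp <- length(phrase)
  n <- length(tokens)
  if (n < lp) return(integer(0))
  starts <- which(tokens == phrase[[1]])
  starts <- starts[starts + lp - 1L <= n]
  if (lp == 1L || !length(starts)) return(starts)
  starts[vapply(starts, function(s) all(tokens[s:(s + lp - 1L)] == phrase), logical(1))]
}

#' Extract diagnostic labels from a report
#'
#' @param report A preprocessed report (character vector of tokens) or raw
#'   text.
#' @param lex A [lexicon()]; default [default_lexicon()].
#' @return A named logical vector over the lexicon's categories
#'   (`TRUE` = positive finding). An empty report is all-negative.
#' @examples
#' extract_labels(c("no", "pleural", "effusion"))
#' extract_labels(c("there", "is", "a", "pleural", "effusion"))
#' @export
extract_labels <- function(report, lex = default_lexicon()) {
  if (is.character(report) && length(report) == 1 && grepl("[^a-z]", report)) {
    report <- tokenize1(report)
  }
  report <- validate_report(report)
  out <- vapply(lex$categories, function(cat) {
    for (phrase in lex$phrases[[cat]]) {
      for (s in phrase_positions(report, phrase)) {
        lo <- max(1L, s - lex$window)
        if (s == 1L || !any(report[lo:(s - 1L)] %in% lex$cues)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  setNames(out, lex$categories)
}

# Logical matrix (reports x categories) of extracted labels.
label_matrix_from_reports <- function(reports, lex) {
  m <- t(vapply(reports, extract_labels, logical(length(lex$categories)), lex = lex))
  colnames(m) <- lex$categories
  m
}

#' Label a whole corpus side
#'
#' @param corpus A corpus tibble (or list of reports).
#' @param lex A [lexicon()].
#' @param side Which side to label when `corpus` is a corpus tibble.
#' @return A tibble with `id` plus one logical column per category.
#' @export
extract_label_table <- function(corpus, lex = default_lexicon(),
                                side = c("reference", "candidate")) {
  side <- match.arg(side)
  reports <- reports_from(corpus, side = side)
  ids <- if (is.data.frame(corpus)) corpus$id else paste0("r", seq_along(reports))
  dplyr::bind_cols(tibble(id = ids),
                   as_tibble(label_matrix_from_reports(reports, lex)))
}

# Coerce a label table (tibble with optional id, matrix, or list of named
# logical vectors) to a logical matrix with category columns.
as_label_matrix <- function(x, categories = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    x <- do.call(rbind, lapply(x, function(v) v[names(x[[1]])]))
  }
  if (is.data.frame(x)) {
    if ("id" %in% names(x)) x <- x[setdiff(names(x), "id")]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) abort("Labels must be a table of reports by categories.")
  storage.mode(x) <- "logical"
  if (!is.null(categories)) {
    if (!setequal(colnames(x), categories)) {
      abort("Label table categories do not match the expected category list.")
    }
    x <- x[, categories, drop = FALSE]
  }
  x
}

#' Agreement between two sets of extracted labels
#'
#' The fraction of (report, category) cells in which candidate and reference
#' labels agree — the "diagnostic accuracy" used to compare report
#' generators. `average = "micro"` pools all cells; `"macro"` averages the
#' per-category accuracies (identical for complete tables, where every
#' category has a value for every report).
#'
#' @param candidates,references Label tables: tibbles from
#'   [extract_label_table()], logical matrices, or lists of named logical
#'   vectors. Must have the same number of reports and the same categories.
#' @param average `"micro"` (default) or `"macro"`.
#' @return A number in \[0, 1\].
#' @examples
#' a <- extract_label_table(report_corpus(c("no pleural effusion")))
#' label_accuracy(a, a)
#' @export
label_accuracy <- function(candidates, references, average = c("micro", "macro")) {
  average <- match.arg(average)
  cand <- as_label_matrix(candidates)
  ref <- as_label_matrix(references, categories = colnames(cand))
  if (nrow(cand) != nrow(ref)) abort("Candidate and reference label tables differ in length.")
  agree <- cand == ref
  if (average == "micro") mean(agree) else mean(colMeans(agree))
}

#' Read / write label tables as CSV
#'
#' The CSV has an `id` column plus one column per category with values in
#' `positive`/`negative` or `1`/`0` — an adapter point for labels produced
#' by external tools.
#'
#' @param path CSV file.
#' @param categories Optional category vector the table must match.
#' @return For `read_label_table`, a tibble with `id` plus logical category
#'   columns.
#' @export
read_label_table <- function(path, categories = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"id" %in% names(df)) abort(sprintf("%s lacks an `id` column.", path))
  cats <- setdiff(names(df), "id")
  if (!is.null(categories)) {
    extra <- setdiff(cats, categories)
    missing <- setdiff(categories, cats)
    if (length(extra)) abort(sprintf("Unknown category column(s): %s.", paste(extra, collapse = ", ")))
    if (length(missing)) abort(sprintf("Missing category column(s): %s.", paste(missing, collapse = ", ")))
    cats <- categories
  }
  parse_cell <- function(v, col) {
    if (anyNA(v)) abort(sprintf("Missing label cell(s) in column `%s`.", col))
    v <- tolower(trimws(v))
    ok <- v %in% c("positive", "negative", "1", "0", "true", "false")
    if (!all(ok)) {
      abort(sprintf("Invalid label value(s) in column `%s`: %s.", col,
                    paste(unique(v[!ok]), collapse = ", ")))
    }
    v %in% c("positive", "1", "true")
  }
  out <- tibble(id = df$id)
  for (col in cats) out[[col]] <- parse_cell(df[[col]], col)
  out
}

#' @rdname read_label_table
#' @param labels A label table (tibble with `id` or logical matrix).
#' @export
write_label_table <- function(labels, path) {
  if (is.data.frame(labels) && "id" %in% names(labels)) {
    ids <- labels$id
    m <- as_label_matrix(labels)
  } else {
    m <- as_label_matrix(labels)
    ids <- paste0("r", seq_len(nrow(m)))
  }
  df <- as_tibble(ifelse(m, "positive", "negative"))
  readr::write_csv(dplyr::bind_cols(tibble(id = ids), df), path, progress = FALSE)
  invisible(path)
}
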