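#' Clean and tokenize raw report text
#'
#' Applies the standard cleaning used throughout the package: text is
#' lowercased, split on every maximal run of non-alphabetic characters, and
#' empty fragments are dropped, so every surviving token consists only of the
#' letters a-z. Stop words are retained and no stemming or lemmatization is
#' applied. Numbers, punctuation and measurement units that contain digits
#' disappear entirely; hyphenated words are split (`"x-ray"` becomes `"x"`,
#' `"ray"`).
#'
#' De-identification placeholders of the form `"xxxx"` (any casing, two or
#' more x's) are removed by default, since they stand for redacted content
#' rather than words. Set `drop_placeholders = FALSE` to keep them as tokens.
#'
#' @param x Character vector of raw report texts. `NA` is treated as the
#'   empty string.
#' @param drop_placeholders Drop runs of two or more x's (de-identification
#'   markers)? Default `TRUE`.
#' @return A list with one character vector of tokens per element of `x`.
#'   Empty input yields an empty token vector, never an error.
#' @examples
#' preprocess_text("The heart is normal.")[[1]]
#' preprocess_text("Heart size 5 cm, XXXX stable.")[[1]]
#' @export
preprocess_text <- function(x, drop_placeholders = TRUE) {
  if (is.null(x)) return(list())
  if (!is.character(x)) x <- as.character(x)
  x[is.na(x)] <- ""
  pieces <- strsplit(tolower(x), "[^a-z]+")
  lapply(pieces, function(tok) {
    tok <- tok[nzchar(tok)]
    if (drop_placeholders && length(tok)) tok <- tok[!grepl("^x{2,}$", tok)]
    tok
  })
}

# Scalar convenience used internally.
tokenize1 <- function(x, drop_placeholders = TRUE) {
  preprocess_text(x, drop_placeholders = drop_placeholders)[[1]]
}

# A report is a character vector of nonempty lowercase alphabetic tokens.
validate_report <- function(tokens, what = "report") {
  if (is.null(tokens)) return(character(0))
  if (!is.character(tokens)) {
    abort(sprintf("A %s must be a character vector of tokens.", what))
  }
  bad <- !grepl("^[a-z]+$", tokens)
  if (any(bad)) {
    abort(sprintf(
      "Invalid token(s) in %s: %s. Tokens must be nonempty, lowercase and alphabetic; run preprocess_text() first.",
      what, paste(unique(tokens[bad]), collapse = ", ")
    ))
  }
  tokens
}

# Coerce raw text, a single token vector, or a list of token vectors into a
# validated list of reports.
as_report_list <- function(x, drop_placeholders = TRUE, what = "report") {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    # Raw text only if anything needs cleaning; a clean token vector of
    # length > 1 is ambiguous, so require lists for pre-tokenized input.
    # NA marks an absent report and stays absent (NULL), not empty.
    out <- preprocess_text(x, drop_placeholders = drop_placeholders)
    out[is.na(x)] <- list(NULL)
    return(out)
  }
  if (is.list(x)) {
    return(lapply(x, function(r) {
      if (is.null(r) || (length(r) == 1 && is.na(r))) {
        NULL
      } else if (length(r) == 1 && is.character(r) && grepl("[^a-z]", r)) {
        tokenize1(r, drop_placeholders)
      } else {
        validate_report(as.character(r), what = what)
      }
    }))
  }
  abort("Reports must be given as a character vector of raw texts or a list of token vectors.")
}
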