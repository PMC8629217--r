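#' Configure the synthetic report generator
#'
#' The generator emulates the statistical structure of screening chest X-ray
#' report corpora: highly standardized sentences drawn from shared template
#' banks covering four anatomical topics (heart size, lungs, heart-related
#' lung problems such as effusion and edema, bony structures), about 70% of
#' reports fully normal, negated findings phrased with cues like "no" /
#' "without", and a per-report ground-truth label vector consistent with a
#' normal/abnormal tag. Mean report length is governed by the template banks
#' themselves (roughly 32 tokens with the bundled banks), not by truncation.
#'
#' @param n_reports Number of reports to generate (default 1000).
#' @param normal_fraction Probability a report is fully normal (default
#'   0.70).
#' @param abnormal_rates Named per-category probabilities of a positive
#'   finding *given* the report is abnormal; at least one finding is always
#'   forced. Defaults cover the template banks' seven expressible findings
#'   with plausible relative prevalences (cardiomegaly and effusion common,
#'   pneumothorax rare).
#' @param templates Path to a template-bank YAML, or a parsed bank from
#'   [read_templates()]; default: the bundled banks.
#' @param lex Lexicon defining the full category list for the ground-truth
#'   label vectors (default [default_lexicon()]); categories the templates
#'   cannot express are always negative.
#' @param seed Integer seed stored in the config and used by
#'   [generate_references()] unless overridden there.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_reports = 1000, normal_fraction = 0.70,
                             abnormal_rates = NULL, templates = NULL,
                             lex = default_lexicon(), seed = NULL) {
  n_reports <- as.integer(n_reports)
  if (is.na(n_reports) || n_reports < 1) abort("`n_reports` must be an integer >= 1.")
  if (normal_fraction < 0 || normal_fraction > 1) abort("`normal_fraction` must be in [0, 1].")
  tmpl <- if (is.null(templates)) {
    read_templates(system.file("extdata", "templates.yaml", package = "reporteval"))
  } else if (is.character(templates)) {
    read_templates(templates)
  } else {
    templates
  }
  active <- unlist(lapply(tmpl$topics, `[[`, "categories"), use.names = FALSE)
  missing <- setdiff(active, lex$categories)
  if (length(missing)) {
    abort(sprintf("Template categories absent from the lexicon: %s.",
                  paste(missing, collapse = ", ")))
  }
  rates <- c(cardiomegaly = 0.35, consolidation = 0.25, pneumothorax = 0.10,
             atelectasis = 0.25, pleural_effusion = 0.30, edema = 0.20,
             fracture = 0.15)
  rates <- rates[intersect(names(rates), active)]
  if (!is.null(abnormal_rates)) {
    bad <- setdiff(names(abnormal_rates), active)
    if (length(bad)) abort(sprintf("Rates for unknown categories: %s.", paste(bad, collapse = ", ")))
    rates[names(abnormal_rates)] <- abnormal_rates
  }
  rates[setdiff(active, names(rates))] <- 0.2
  rates <- rates[active]
  if (any(rates < 0 | rates > 1)) abort("Abnormality rates must be in [0, 1].")
  structure(
    list(n_reports = n_reports, normal_fraction = normal_fraction,
         abnormal_rates = rates, templates = tmpl, lexicon = lex, seed = seed),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d reports, %.0f%% normal, findings: %s\n",
              x$n_reports, 100 * x$normal_fraction,
              paste(names(x$abnormal_rates), collapse = ", ")))
  invisible(x)
}

#' @rdname generator_config
#' @param path A template-bank YAML with keys `opening` (shared sentences),
#'   `topic_order`, and `topics` (per topic: `categories`, `normal`
#'   sentences, `abnormal` sentences per category).
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- yaml::read_yaml(path)
  toks <- function(ss) lapply(as.list(ss), function(s) validate_report(tokenize1(s), "template sentence"))
  tmpl <- list(
    opening = toks(raw$opening %||% list()),
    topic_order = unlist(raw$topic_order),
    topics = lapply(raw$topics, function(tp) {
      ab <- lapply(tp$abnormal, toks)
      if (!length(tp$normal)) abort("Every topic needs >= 1 normal template.")
      if (!setequal(names(ab), tp$categories) || any(lengths(ab) == 0)) {
        abort("Every template category needs >= 1 abnormal sentence.")
      }
      list(categories = unlist(tp$categories), normal = toks(tp$normal), abnormal = ab)
    })
  )
  if (!setequal(tmpl$topic_order, names(tmpl$topics))) {
    abort("`topic_order` must list exactly the topics defined under `topics`.")
  }
  tmpl$vocabulary <- sort(unique(unlist(c(
    tmpl$opening,
    lapply(tmpl$topics, function(tp) c(tp$normal, unlist(tp$abnormal, recursive = FALSE)))
  ), use.names = FALSE)))
  tmpl
}

sample1 <- function(x) x[[sample.int(length(x), 1L)]]

# Render one report from a named logical label vector (ambient RNG).
render_report <- function(labels, tmpl) {
  sents <- list()
  if (length(tmpl$opening)) sents <- c(sents, list(sample1(tmpl$opening)))
  for (topic in tmpl$topic_order) {
    tp <- tmpl$topics[[topic]]
    pos <- tp$categories[labels[tp$categories]]
    if (length(pos)) {
      for (cat in pos) sents <- c(sents, list(sample1(tp$abnormal[[cat]])))
    } else {
      sents <- c(sents, list(sample1(tp$normal)))
    }
  }
  unlist(sents, use.names = FALSE)
}

# Draw one ground-truth label vector over the lexicon's categories.
sample_labels <- function(config) {
  labels <- setNames(rep(FALSE, length(config$lexicon$categories)),
                     config$lexicon$categories)
  if (stats::runif(1) >= config$normal_fraction) {
    rates <- config$abnormal_rates
    pos <- stats::runif(length(rates)) < rates
    if (!any(pos)) pos[sample.int(length(rates), 1L, prob = rates)] <- TRUE
    labels[names(rates)[pos]] <- TRUE
  }
  labels
}

#' Generate a synthetic reference corpus
#'
#' Draws per-report ground-truth finding labels (fully normal with
#' probability `normal_fraction`, otherwise at least one positive finding),
#' renders each report through the template banks, and tags it `"normal"`
#' exactly when every label is negative. Deterministic under a seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to the config's.
#' @return A tibble with columns `id`, `reference` (token list-column),
#'   `tag`, and one logical column per lexicon category (the true label
#'   vector). The config is attached as attribute `"generator_config"`.
#' @examples
#' records <- generate_references(generator_config(n_reports = 5, seed = 1))
#' records$tag
#' @export
generate_references <- function(config, seed = NULL) {
  if (!inherits(config, "generator_config")) abort("`config` must come from generator_config().")
  seed <- seed %||% config$seed
  n <- config$n_reports
  cats <- config$lexicon$categories
  with_seed_if(seed, {
    labels <- t(vapply(seq_len(n), function(i) sample_labels(config), logical(length(cats))))
    colnames(labels) <- cats
    reports <- lapply(seq_len(n), function(i) render_report(labels[i, ], config$templates))
    out <- tibble(
      id = sprintf("syn%05d", seq_len(n)),
      reference = reports,
      tag = ifelse(rowSums(labels) == 0, "normal", "abnormal")
    )
    out <- dplyr::bind_cols(out, as_tibble(labels))
    attr(out, "generator_config") <- config
    out
  })
}

# True-label matrix of a generated record set.
record_labels <- function(records) {
  config <- attr(records, "generator_config")
  if (is.null(config)) abort("`records` must come from generate_references().")
  as_label_matrix(records[config$lexicon$categories])
}

#' Simulate a report generator with tunable input-conditioning
#'
#' Emulates a generation model whose dependence on its input can be dialed
#' from zero to perfect: for each record the candidate is rendered from the
#' record's *own* true labels with probability `rho` (conditioning
#' strength), and otherwise from the label vector of a uniformly drawn
#' record of the corpus (the corpus marginal — an unconditioned draw). The
#' rendered candidate is then corrupted token-wise at rate `noise` by
#' substituting random in-vocabulary tokens, so cleaning invariants still
#' hold.
#'
#' At `rho = 1, noise = 0` the candidates' extracted labels reproduce the
#' true labels exactly; at `rho = 0` the model is fully unconditioned and
#' permuting its candidates changes nothing statistically.
#'
#' @param records Output of [generate_references()].
#' @param rho Conditioning strength in \[0, 1\].
#' @param noise Word-corruption rate in \[0, 1\] (default 0).
#' @param seed Integer seed (optional).
#' @return `records` with a `candidate` list-column added (a corpus tibble
#'   ready for [evaluate_metrics()], [permute_candidates()], ...).
#' @export
simulate_model <- function(records, rho, noise = 0, seed = NULL) {
  config <- attr(records, "generator_config")
  if (is.null(config)) abort("`records` must come from generate_references().")
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1].")
  if (noise < 0 || noise > 1) abort("`noise` must be in [0, 1].")
  labels <- record_labels(records)
  n <- nrow(records)
  vocab <- config$templates$vocabulary
  out <- records
  out$candidate <- with_seed_if(seed, {
    lapply(seq_len(n), function(i) {
      src <- if (stats::runif(1) < rho) i else sample.int(n, 1L)
      cand <- render_report(labels[src, ], config$templates)
      if (noise > 0 && length(cand)) {
        corrupt <- stats::runif(length(cand)) < noise
        if (any(corrupt)) {
          cand[corrupt] <- vocab[sample.int(length(vocab), sum(corrupt), replace = TRUE)]
        }
      }
      cand
    })
  })
  out
}
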