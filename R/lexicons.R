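#' Load the model / oncological / organotypic-process lexicons
#'
#' A lexicon maps canonical terms to their surface variants (case and
#' spelling/plural variants, hyphen/space tolerant). The shipped default
#' carries the platform search vocabulary (organoid, enteroid, colonoid,
#' assembloid, gastruloid, iblastoid, tumoroid, blastoid, the on-chip variants
#' and the microphysiological-system spellings), an oncological term list and
#' the organotypic processes that may precede an on-chip suffix.
#'
#' Within one lexicon every surface variant must map to exactly one canonical
#' term; violations are a configuration error.
#'
#' @param path Path to a lexicons YAML file; `NULL` for the shipped default.
#' @return A list of tibbles: `model_terms` (columns `canonical`, `variant`,
#'   `class`, `oncological`, `never_tumor`, `requires`), `oncological_terms`
#'   and `organotypic_processes` (columns `canonical`, `variant`).
#' @export
load_lexicons <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lexicons.yaml", package = "oncolit")
  cfg <- yaml::read_yaml(path)
  model <- purrr::imap(cfg$model_terms, function(entry, canon) {
    tibble(
      canonical = canon,
      variant = stringr::str_to_lower(unlist(entry$variants)),
      class = entry$class %||% "organoid",
      oncological = isTRUE(entry$oncological),
      never_tumor = isTRUE(entry$never_tumor),
      requires = entry$requires %||% NA_character_
    )
  }) %>% bind_rows()
  flat <- function(block, name) {
    out <- purrr::imap(block, function(vars, canon) {
      tibble(canonical = canon, variant = stringr::str_to_lower(unlist(vars)))
    }) %>% bind_rows()
    validate_lexicon(out, name)
    out
  }
  validate_lexicon(model, "model_terms")
  list(
    model_terms = model,
    oncological_terms = flat(cfg$oncological_terms, "oncological_terms"),
    organotypic_processes = flat(cfg$organotypic_processes, "organotypic_processes")
  )
}

validate_lexicon <- function(lex, name) {
  dup <- lex %>%
    distinct(.data$canonical, .data$variant) %>%
    count(.data$variant) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "lexicon '%s': variant(s) mapped to more than one canonical term: %s",
      name, paste(dup$variant, collapse = ", ")
    ))
  }
  invisible(lex)
}

#' Load the nested research-topic lexicon
#'
#' First-level topic ids are grouped into panels (models, therapy,
#' pharmacology, physiology, immune cells, cellular processes, techniques);
#' second-level lists hold the surface variants captured in titles, keywords
#' and abstracts. Every variant must belong to exactly one topic.
#'
#' @param path Path to a topics YAML file; `NULL` for the shipped default.
#' @return A tibble with columns `panel`, `topic`, `variant`.
#' @export
load_topic_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "topics.yaml", package = "oncolit")
  cfg <- yaml::read_yaml(path)
  out <- purrr::imap(cfg$panels, function(topics, panel) {
    purrr::imap(topics, function(vars, topic) {
      tibble(panel = panel, topic = topic, variant = stringr::str_to_lower(unlist(vars)))
    }) %>% bind_rows()
  }) %>% bind_rows()
  dup <- out %>% count(.data$variant) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "topic lexicon: variant(s) in more than one topic: %s",
      paste(dup$variant, collapse = ", ")
    ))
  }
  out
}
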