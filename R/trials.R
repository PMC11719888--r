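#' @title Clinical-trial registry classification
#' @description
#' Classifies registry exports (legacy ClinicalTrials-style CSV with
#' Conditions / Study Designs / Status columns) by platform mention, primary
#' purpose and tumor group, reusing the publication classifier's lexicons and
#' taxonomy so tumor types are grouped consistently across the two analyses.
#' @name trials
NULL

# Registry search-term sets for the two platforms.
trial_term_sets <- function() {
  list(
    organoid_terms = c(
      "organoid", "organoids", "enteroid", "enteroids", "colonoid",
      "colonoids", "tumoroid", "tumoroids", "tumouroid", "tumouroids"
    ),
    onchip_terms = c("on-chip", "on-chips", "on-a-chip")
  )
}

#' Parse a clinical-trial registry export
#'
#' One record per row; withdrawn trials are excluded when a status column is
#' present. Platform term sets are matched against the title and conditions
#' text; trials matching neither set are dropped (they would not have been
#' retrieved by the registry search).
#'
#' @param table A data frame (or CSV file path) with at least `Conditions`
#'   and `Study Designs` columns; `NCT Number`/`Trial ID`, `Title` and
#'   `Status` are used when present.
#' @param col_map Named character vector mapping the expected roles
#'   (`trial_id`, `title`, `conditions`, `study_design`, `status`) to column
#'   names, for exports with other headers.
#' @return A tibble `trial_id`, `title`, `conditions`, `study_design`,
#'   `status`, `organoid_terms`, `onchip_terms`.
#' @export
parse_trials <- function(table, col_map = NULL) {
  if (is.character(table)) {
    table <- utils::read.csv(table, check.names = FALSE, stringsAsFactors = FALSE)
  }
  table <- as_tibble(table)
  defaults <- c(
    trial_id = "NCT Number", title = "Title", conditions = "Conditions",
    study_design = "Study Designs", status = "Status"
  )
  col_map <- c(col_map, defaults[setdiff(names(defaults), names(col_map))])
  pick <- function(role, required = FALSE) {
    nm <- col_map[[role]]
    if (!nm %in% names(table)) {
      if (required) abort(sprintf("required column '%s' (%s) missing", nm, role))
      return(rep(NA_character_, nrow(table)))
    }
    as.character(table[[nm]])
  }
  out <- tibble(
    trial_id = pick("trial_id"),
    title = normalize_text(pick("title")),
    conditions = normalize_text(pick("conditions", required = TRUE)),
    study_design = normalize_text(pick("study_design", required = TRUE)),
    status = pick("status")
  )
  if (all(is.na(out$trial_id))) out$trial_id <- paste0("trial_", seq_len(nrow(out)))
  out <- out %>%
    filter(is.na(.data$status) | stringr::str_to_lower(.data$status) != "withdrawn")
  sets <- trial_term_sets()
  text <- stringr::str_to_lower(paste(out$title, out$conditions, sep = " "))
  match_set <- function(terms) {
    pat <- paste(purrr::map_chr(terms, variant_regex), collapse = "|")
    stringr::str_detect(text, stringr::regex(pat, ignore_case = TRUE))
  }
  out %>%
    mutate(
      organoid_terms = match_set(sets$organoid_terms),
      onchip_terms = match_set(sets$onchip_terms)
    ) %>%
    filter(.data$organoid_terms | .data$onchip_terms)
}

#' Extract the primary purpose from a study-design field
#'
#' The registry's design column is pipe-delimited
#' (`Allocation: ...|Intervention Model: ...|Primary Purpose: ...`); the
#' label following the `Primary Purpose:` key is returned, trimmed.
#'
#' @param study_design Character vector of design strings.
#' @return Character vector of purpose labels (`"unspecified"` when the key
#'   is absent).
#' @export
extract_primary_purpose <- function(study_design) {
  m <- stringr::str_match(
    study_design %||% "",
    stringr::regex("primary purpose:\\s*([^|]*)", ignore_case = TRUE)
  )[, 2]
  out <- stringr::str_trim(m)
  out[is.na(out) | !nzchar(out)] <- "unspecified"
  out
}

#' Map trial condition text to tumor groups
#'
#' Organ aliases found in the conditions text are resolved through the same
#' taxonomy rules as publication organ models, so tumor types are
#' consistently grouped across publications and trials.
#'
#' @param conditions Character vector of condition strings.
#' @param taxonomy A [load_taxonomy()] object.
#' @return Character vector of resolved category ids (see
#'   [assign_hierarchy()]).
#' @export
classify_trial_condition <- function(conditions, taxonomy = load_taxonomy()) {
  purrr::map_chr(conditions, function(txt) {
    hits <- locate_lexicon(
      normalize_text(txt %||% ""),
      taxonomy$aliases %>% rename(canonical = "canonical")
    )
    assign_hierarchy(unique(hits$canonical), taxonomy)
  })
}

#' Classify a whole trial table
#'
#' @param trials Tibble from [parse_trials()].
#' @param taxonomy A [load_taxonomy()] object.
#' @return The input with `purpose` and `tumor_group` columns added.
#' @export
classify_trials <- function(trials, taxonomy = load_taxonomy()) {
  trials %>%
    mutate(
      purpose = extract_primary_purpose(.data$study_design),
      tumor_group = classify_trial_condition(.data$conditions, taxonomy)
    )
}
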