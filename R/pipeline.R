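#' Pipeline configuration
#'
#' Bundles the configuration of an end-to-end run: config file paths (shipped
#' defaults when `NULL`), the early/recent period boundary, the trend
#' threshold, the regrouping scheme and the year ranges.
#'
#' @param lexicons,taxonomy,topics,geography Paths to YAML configs (`NULL`
#'   for shipped defaults).
#' @param overrides Optional override table (tibble or CSV path) forwarded to
#'   [apply_overrides()].
#' @param boundary First year of the recent period (default 2020).
#' @param threshold Trend threshold (default 0.4, i.e. the 40% rule).
#' @param scheme Regrouping scheme for comparison exports.
#' @param start First collected year (default 2011).
#' @param fit_years Year range for the growth regression.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lexicons = NULL, taxonomy = NULL, topics = NULL,
                            geography = NULL, overrides = NULL,
                            boundary = 2020L, threshold = 0.4,
                            scheme = "default", start = 2011L,
                            fit_years = 2011:2022, seed = 1L) {
  if (threshold <= 0) abort("threshold must be > 0")
  structure(
    list(
      lexicons = lexicons, taxonomy = taxonomy, topics = topics,
      geography = geography, overrides = overrides, boundary = as.integer(boundary),
      threshold = threshold, scheme = scheme, start = as.integer(start),
      fit_years = as.integer(fit_years), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# deterministic CSV writer (fixed field order, no timestamps)
write_export <- function(df, path) {
  flat <- df %>% mutate(across(dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ";")))
  utils::write.csv(flat, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' ingest -> dedup/merge -> classify -> taxonomy -> topics -> geography ->
#' trends -> growth (-> trials), writing the deterministic table exports
#' behind each figure plus a run manifest with stage counts. Identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param inputs Character vector of metadata file paths (dialect inferred
#'   from extension), or an already-parsed corpus tibble.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for CSV exports and `manifest.json`;
#'   `NULL` to skip writing.
#' @param update Optional update-acquisition corpus (tibble or file paths)
#'   merged via [merge_acquisitions()].
#' @param trials Optional clinical-trials table (tibble or CSV path).
#' @return A list of result tibbles (`corpus`, `assignments`, `resolutions`,
#'   `topics`, `geography`, `trends`, `matrix`, `growth`, `trials`,
#'   `manifest`).
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL,
                         update = NULL, trials = NULL) {
  lexicons <- load_lexicons(config$lexicons)
  taxonomy <- load_taxonomy(config$taxonomy)
  topic_lex <- load_topic_lexicon(config$topics)
  geo <- load_geo_config(config$geography)

  as_corpus <- function(x) {
    if (is.data.frame(x)) return(x)
    purrr::map(x, parse_metadata_file) %>% bind_rows()
  }
  raw <- as_corpus(inputs)
  n_ingested <- nrow(raw)
  corpus <- filter_document_types(raw)
  n_after_type_filter <- nrow(corpus)
  corpus <- dedup_corpus(corpus)
  if (!is.null(update)) {
    upd <- dedup_corpus(filter_document_types(as_corpus(update)))
    corpus <- merge_acquisitions(corpus, upd)
  }
  n_deduplicated <- nrow(corpus)

  overrides <- config$overrides
  if (is.character(overrides)) {
    overrides <- as_tibble(utils::read.csv(overrides, stringsAsFactors = FALSE))
  }
  assignments <- classify_corpus(corpus, lexicons, taxonomy, overrides)
  resolutions <- resolve_organs(assignments, taxonomy, "default")
  topic_tab <- annotate_topics(corpus, topic_lex)
  attributions <- attribute_countries(corpus, geo)
  geography <- aggregate_geography(attributions, geo)

  in_corpus <- function(name) {
    assignments$record_id[purrr::map_lgl(assignments$corpora, ~ name %in% .x)]
  }
  tumor_org <- corpus %>% filter(.data$record_id %in% in_corpus("tumor_organoid"))
  trends <- category_trends(
    tumor_org, resolutions %>% filter(.data$record_id %in% tumor_org$record_id),
    taxonomy, config$boundary, config$start, config$threshold
  )
  groups <- resolutions %>%
    filter(.data$record_id %in% tumor_org$record_id) %>%
    mutate(group = regroup_for_scheme(.data$node, taxonomy, "system")) %>%
    select("record_id", "group")
  matrix_tab <- trend_matrix(
    tumor_org, groups, topic_tab %>% select("record_id", "topic"),
    config$boundary, config$start, config$threshold
  )

  series <- yearly_counts(tumor_org, config$fit_years)
  growth <- if (nrow(series) >= 4 && all(series$count > 0)) {
    fit <- fit_loglinear(series)
    glance(fit) %>% mutate(a = fit$a, b = fit$b, corpus = "tumor_organoid")
  } else {
    tibble()
  }

  trials_tab <- if (!is.null(trials)) {
    classify_trials(parse_trials(trials), taxonomy)
  } else {
    tibble()
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    stage_counts = list(
      ingested = n_ingested,
      after_type_filter = n_after_type_filter,
      excluded_types = n_ingested - n_after_type_filter,
      deduplicated = n_deduplicated,
      classified = nrow(assignments),
      organoid = length(in_corpus("organoid")),
      tumor_organoid = length(in_corpus("tumor_organoid")),
      ooc = length(in_corpus("ooc")),
      toc = length(in_corpus("toc")),
      trials = nrow(trials_tab)
    )
  )

  out <- list(
    corpus = corpus, assignments = assignments, resolutions = resolutions,
    topics = topic_tab, geography = geography, trends = trends,
    matrix = matrix_tab, growth = growth, trials = trials_tab,
    manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_corpus(corpus, file.path(out_dir, "corpus.jsonl"))
    write_export(assignments, file.path(out_dir, "assignments.csv"))
    write_export(resolutions, file.path(out_dir, "resolutions.csv"))
    write_export(topic_tab, file.path(out_dir, "topics.csv"))
    write_export(geography, file.path(out_dir, "geography.csv"))
    write_export(trends, file.path(out_dir, "trends.csv"))
    write_export(matrix_tab, file.path(out_dir, "matrix.csv"))
    if (nrow(growth) > 0) write_export(growth, file.path(out_dir, "growth.csv"))
    if (nrow(trials_tab) > 0) write_export(trials_tab, file.path(out_dir, "trials.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Incidence / mortality / research / trials comparison table
#'
#' For each tumor group: its share of global incidence, global mortality,
#' tumor-organoid research articles, ToC research articles and clinical
#' trials. Every column is normalized to sum to 1 over the included groups;
#' research and trial counts are first mapped through the regrouping scheme
#' so the groups are comparable with the statistics source (e.g.
#' cholangiocarcinoma counted with liver).
#'
#' @param organ_counts Named list of tibbles `group`, `n` (e.g.
#'   `tumor_organoid`, `toc`, `trials`), already regrouped.
#' @param constants Path to a constants YAML (`NULL` for the shipped
#'   file) or a tibble `group`, `incidence`, `mortality`.
#' @return A tibble `group`, one share column per source; each column sums
#'   to 1.
#' @export
export_comparison_table <- function(organ_counts, constants = NULL) {
  if (is.null(constants) || is.character(constants)) {
    path <- constants %||%
      system.file("extdata", "comparison_constants.yaml", package = "oncolit")
    cfg <- yaml::read_yaml(path)
    constants <- purrr::imap(cfg$groups, function(x, g) {
      tibble(group = g, incidence = x$incidence, mortality = x$mortality)
    }) %>% bind_rows()
  }
  groups_used <- sort(unique(unlist(purrr::map(organ_counts, "group"))))
  missing <- setdiff(groups_used, constants$group)
  if (length(missing) > 0) {
    abort(sprintf(
      "group(s) missing from comparison constants: %s",
      paste(missing, collapse = ", ")
    ))
  }
  base <- constants %>%
    filter(.data$group %in% groups_used) %>%
    mutate(
      incidence = .data$incidence / sum(.data$incidence),
      mortality = .data$mortality / sum(.data$mortality)
    )
  for (nm in names(organ_counts)) {
    oc <- organ_counts[[nm]] %>%
      group_by(.data$group) %>%
      summarise(n = sum(.data$n), .groups = "drop")
    base <- base %>%
      left_join(oc, by = "group") %>%
      mutate(
        !!nm := tidyr::replace_na(.data$n, 0) / sum(oc$n)
      ) %>%
      select(-"n")
  }
  base
}
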