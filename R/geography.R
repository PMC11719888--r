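#' Load the country gazetteer, ERA membership and population snapshot
#'
#' @param path Path to a geography YAML file; `NULL` for the shipped default
#'   (common name variants, an approximate population snapshot and European
#'   Research Area membership: EU-27 incl. the former member UK plus 18
#'   associated countries).
#' @return A `geo_config` list: `gazetteer` tibble (`country`, `variant`),
#'   `countries` tibble (`country`, `population`, `era_member`), `snapshot`.
#' @export
load_geo_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "geography.yaml", package = "oncolit")
  cfg <- yaml::read_yaml(path)
  gaz <- purrr::map(cfg$countries, function(x) {
    tibble(country = x$name, variant = unlist(x$variants %||% x$name))
  }) %>% bind_rows()
  countries <- purrr::map(cfg$countries, function(x) {
    tibble(
      country = x$name, population = as.numeric(x$population),
      era_member = isTRUE(x$era)
    )
  }) %>% bind_rows()
  structure(
    list(gazetteer = gaz, countries = countries, snapshot = cfg$snapshot),
    class = "geo_config"
  )
}

#' Count country/region mentions in an affiliation block
#'
#' Every gazetteer name occurrence in the author address text is counted;
#' longer variants win overlaps (so "South Korea" is never also counted as
#' "Korea"). The first-occurrence character offset is recorded per country.
#'
#' @param affiliation_text Concatenated author addresses for one record.
#' @param geo A [load_geo_config()] object.
#' @return A tibble `country`, `n`, `first_offset`, ordered by `first_offset`.
#' @export
count_country_mentions <- function(affiliation_text, geo = load_geo_config()) {
  lex <- geo$gazetteer %>% rename(canonical = "country")
  hits <- locate_lexicon(affiliation_text %||% "", lex)
  if (nrow(hits) == 0) {
    return(tibble(country = character(), n = integer(), first_offset = integer()))
  }
  hits %>%
    group_by(country = .data$canonical) %>%
    summarise(n = dplyr::n(), first_offset = min(.data$start), .groups = "drop") %>%
    arrange(.data$first_offset)
}

#' Main research country of a record
#'
#' The country with the highest mention count; ties are broken by the
#' earliest first mention, which typically represents the first author's
#' country. Empty counts give `NA`.
#'
#' @param counts Tibble from [count_country_mentions()].
#' @return Country name or `NA_character_`.
#' @export
main_country <- function(counts) {
  if (nrow(counts) == 0) return(NA_character_)
  counts %>%
    arrange(dplyr::desc(.data$n), .data$first_offset) %>%
    slice(1) %>%
    pull("country")
}

#' Fractional country contributions of a record
#'
#' Each country's fraction is its mention count divided by the total number
#' of occurrences of all country/region names; fractions sum to 1 for
#' non-empty counts.
#'
#' @param counts Tibble from [count_country_mentions()].
#' @return The input with a `fraction` column added.
#' @export
fractional_contributions <- function(counts) {
  if (nrow(counts) == 0) return(mutate(counts, fraction = numeric()))
  mutate(counts, fraction = .data$n / sum(.data$n))
}

#' Attribute every record of a corpus to countries
#'
#' @param corpus A corpus tibble.
#' @param geo A [load_geo_config()] object.
#' @return A tibble `record_id`, `country`, `n`, `first_offset`, `fraction`,
#'   `is_main` (one `TRUE` row per record with any mention).
#' @export
attribute_countries <- function(corpus, geo = load_geo_config()) {
  out <- purrr::map(seq_len(nrow(corpus)), function(i) {
    counts <- count_country_mentions(corpus$affiliation_text[i], geo)
    if (nrow(counts) == 0) return(NULL)
    fractional_contributions(counts) %>%
      mutate(
        record_id = corpus$record_id[i],
        is_main = .data$country == main_country(counts)
      )
  }) %>%
    purrr::compact() %>%
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(
      record_id = character(), country = character(), n = integer(),
      first_offset = integer(), fraction = numeric(), is_main = logical()
    ))
  }
  out %>% select("record_id", "country", "n", "first_offset", "fraction", "is_main")
}

#' Aggregate geographic attributions to a per-country table
#'
#' Per country: number of records for which it is the main country, summed
#' fractional contributions, ERA membership and population-adjusted activity
#' (fractional sum per million inhabitants). An optional grouping table adds
#' per-organ-group breakdowns (the pie-table export). The ERA rollup is
#' appended as a pseudo-country row `"ERA"` summing over members.
#'
#' @param attributions Tibble from [attribute_countries()].
#' @param geo A [load_geo_config()] object.
#' @param groups Optional tibble `record_id`, `group`; when supplied the
#'   table is computed per group.
#' @return A tibble `group` (if requested), `country`, `n_main`, `frac_sum`,
#'   `era_member`, `frac_per_million`, with a final ERA rollup row per group.
#' @export
aggregate_geography <- function(attributions, geo = load_geo_config(),
                                groups = NULL) {
  if (!is.null(groups)) {
    attributions <- inner_join(attributions, groups, by = "record_id")
    gvar <- "group"
  } else {
    attributions <- mutate(attributions, group = "all")
    gvar <- NULL
  }
  if (nrow(attributions) == 0) {
    return(tibble(
      group = character(), country = character(), n_main = integer(),
      frac_sum = numeric(), era_member = logical(), frac_per_million = numeric()
    ))
  }
  missing <- setdiff(unique(attributions$country), geo$countries$country)
  if (length(missing) > 0) {
    abort(sprintf("country missing from config: %s", paste(missing, collapse = ", ")))
  }
  base <- attributions %>%
    group_by(.data$group, .data$country) %>%
    summarise(
      n_main = sum(.data$is_main),
      frac_sum = sum(.data$fraction),
      .groups = "drop"
    ) %>%
    left_join(geo$countries, by = "country") %>%
    filter(!is.na(.data$population)) %>%
    mutate(frac_per_million = .data$frac_sum / (.data$population / 1e6)) %>%
    select("group", "country", "n_main", "frac_sum", "era_member", "frac_per_million")
  era <- base %>%
    filter(.data$era_member) %>%
    group_by(.data$group) %>%
    summarise(
      country = "ERA", n_main = sum(.data$n_main), frac_sum = sum(.data$frac_sum),
      era_member = TRUE,
      frac_per_million = sum(.data$frac_sum) /
        (sum(geo$countries$population[geo$countries$era_member]) / 1e6),
      .groups = "drop"
    )
  out <- bind_rows(arrange(base, .data$group, dplyr::desc(.data$frac_sum)), era)
  if (is.null(gvar)) out <- select(out, -"group")
  out
}
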