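#' Count research articles in the early and recent periods
#'
#' Only research articles (doc_type `article`) are counted. The early period
#' is 2011 up to the year before the boundary (2011-2019 with the default
#' boundary); the recent period is the boundary year onward.
#'
#' @param records Tibble with at least `year` and `doc_type` (a corpus,
#'   possibly pre-filtered to a group/topic selection).
#' @param boundary First year of the recent period (default 2020).
#' @param start First collected year (default 2011).
#' @return Named integer vector `c(n_early, n_recent)`.
#' @export
count_by_period <- function(records, boundary = 2020L, start = 2011L) {
  arts <- records %>% filter(.data$doc_type == "article", .data$year >= start)
  c(
    n_early = sum(arts$year < boundary),
    n_recent = sum(arts$year >= boundary)
  )
}

#' Build one trend cell from period counts
#'
#' `raw_ratio = n_recent / n_early` (defined only when `n_early > 0`) and
#' `adjusted_ratio = raw_ratio / reference_ratio`, the reference being the
#' corpus-wide (or tumor-group-wide) recent/early ratio. Relative changes
#' greater than 40% are labelled: `high` when `adjusted_ratio > 1.4`, `low`
#' when `< 0.6`, `moderate` in between (boundary values are moderate; the
#' thresholds are strict inequalities). `n_early = 0` with `n_recent > 0` is
#' `new`; both zero is `empty`.
#'
#' @param n_early,n_recent Period counts.
#' @param reference_ratio Positive reference ratio for adjustment.
#' @param threshold Relative-change threshold (default 0.4).
#' @return A one-row tibble: `n_early`, `n_recent`, `raw_ratio`,
#'   `adjusted_ratio`, `category`.
#' @export
trend_category <- function(n_early, n_recent, reference_ratio = 1,
                           threshold = 0.4) {
  if (!is.finite(reference_ratio) || reference_ratio <= 0) {
    abort("reference_ratio must be > 0")
  }
  if (threshold <= 0) abort("threshold must be > 0")
  n_early <- unname(n_early); n_recent <- unname(n_recent)
  reference_ratio <- unname(reference_ratio)
  if (n_early == 0 && n_recent == 0) {
    return(tibble(
      n_early = 0L, n_recent = 0L, raw_ratio = NA_real_,
      adjusted_ratio = NA_real_, category = "empty"
    ))
  }
  if (n_early == 0) {
    return(tibble(
      n_early = 0L, n_recent = as.integer(n_recent), raw_ratio = NA_real_,
      adjusted_ratio = NA_real_, category = "new"
    ))
  }
  raw <- n_recent / n_early
  adj <- raw / reference_ratio
  category <- if (adj > 1 + threshold) "high" else if (adj < 1 - threshold) "low" else "moderate"
  tibble(
    n_early = as.integer(n_early), n_recent = as.integer(n_recent),
    raw_ratio = raw, adjusted_ratio = adj, category = category
  )
}

#' Trend matrix of tumor groups by research topics
#'
#' Reproduces the correlation-matrix exports: one top "trend" row per group
#' showing the raw (unadjusted) group fold change between periods, and one
#' cell per group-topic combination whose reference is its own group's
#' recent/early ratio. A sphere-size column `n_total = n_early + n_recent`
#' is included.
#'
#' @param records Corpus tibble (research articles are selected internally).
#' @param groups Tibble `record_id`, `group` (one resolved group per record).
#' @param topics Tibble `record_id`, `topic` from [annotate_topics()].
#' @param boundary,start,threshold See [count_by_period()] and
#'   [trend_category()].
#' @return A `trend_matrix` tibble: `group`, `topic` (`NA` for the top trend
#'   row), `n_early`, `n_recent`, `n_total`, `raw_ratio`, `reference_ratio`,
#'   `adjusted_ratio`, `category`.
#' @export
trend_matrix <- function(records, groups, topics, boundary = 2020L,
                         start = 2011L, threshold = 0.4) {
  recs <- records %>% inner_join(groups, by = "record_id")
  group_ids <- sort(unique(groups$group))
  topic_ids <- sort(unique(topics$topic))
  rows <- list()
  for (g in group_ids) {
    grecs <- recs %>% filter(.data$group == g)
    gp <- count_by_period(grecs, boundary, start)
    # top row: raw group fold change, no adjustment
    top <- trend_category(gp["n_early"], gp["n_recent"], 1, threshold)
    rows[[length(rows) + 1L]] <- top %>%
      mutate(group = g, topic = NA_character_, reference_ratio = 1)
    gref <- if (gp["n_early"] > 0) gp["n_recent"] / gp["n_early"] else NA_real_
    for (tp in topic_ids) {
      ids <- topics$record_id[topics$topic == tp]
      cell_recs <- grecs %>% filter(.data$record_id %in% ids)
      cp <- count_by_period(cell_recs, boundary, start)
      cell <- if (is.na(gref) || gref <= 0) {
        trend_category(cp["n_early"], cp["n_recent"], 1, threshold) %>%
          mutate(adjusted_ratio = NA_real_, category = ifelse(
            .data$category %in% c("new", "empty"), .data$category, "moderate"
          ))
      } else {
        trend_category(cp["n_early"], cp["n_recent"], gref, threshold)
      }
      rows[[length(rows) + 1L]] <- cell %>%
        mutate(group = g, topic = tp, reference_ratio = ifelse(is.na(gref), NA_real_, gref))
    }
  }
  out <- if (length(rows) == 0) {
    tibble(
      group = character(), topic = character(), n_early = integer(),
      n_recent = integer(), n_total = integer(), raw_ratio = numeric(),
      reference_ratio = numeric(), adjusted_ratio = numeric(),
      category = character()
    )
  } else {
    bind_rows(rows) %>%
      mutate(n_total = .data$n_early + .data$n_recent) %>%
      select(
        "group", "topic", "n_early", "n_recent", "n_total",
        "raw_ratio", "reference_ratio", "adjusted_ratio", "category"
      )
  }
  class(out) <- c("trend_matrix", class(out))
  out
}

#' Per-category trend table for a classified corpus
#'
#' The organ-trend export: per resolved taxonomy category, early/recent
#' research-article counts and the trend adjusted for the relative increase
#' in the entire corpus.
#'
#' @param records Corpus tibble.
#' @param resolutions Tibble `record_id`, `node` from [resolve_organs()].
#' @param taxonomy A [load_taxonomy()] object (for node paths).
#' @param boundary,start,threshold See [trend_category()].
#' @return A tibble `node`, `node_path`, `n_early`, `n_recent`, `n_total`,
#'   `raw_ratio`, `adjusted_ratio`, `category`.
#' @export
category_trends <- function(records, resolutions, taxonomy = load_taxonomy(),
                            boundary = 2020L, start = 2011L, threshold = 0.4) {
  corpus_p <- count_by_period(records, boundary, start)
  ref <- if (corpus_p["n_early"] > 0) corpus_p["n_recent"] / corpus_p["n_early"] else 1
  recs <- records %>% inner_join(resolutions, by = "record_id")
  if (nrow(resolutions) == 0) {
    return(tibble(
      node = character(), node_path = character(), n_early = integer(),
      n_recent = integer(), n_total = integer(), raw_ratio = numeric(),
      adjusted_ratio = numeric(), category = character()
    ))
  }
  purrr::map(sort(unique(resolutions$node)), function(nd) {
    p <- count_by_period(recs %>% filter(.data$node == nd), boundary, start)
    trend_category(p["n_early"], p["n_recent"], ref, threshold) %>%
      mutate(node = nd, node_path = node_path(taxonomy, nd))
  }) %>%
    bind_rows() %>%
    mutate(n_total = .data$n_early + .data$n_recent) %>%
    select(
      "node", "node_path", "n_early", "n_recent", "n_total",
      "raw_ratio", "adjusted_ratio", "category"
    )
}
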