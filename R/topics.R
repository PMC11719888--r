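#' Annotate records with research topics
#'
#' A topic is present iff any of its surface variants occurs (case-insensitive,
#' word-bounded, hyphen/space tolerant) in the title, keywords or abstract.
#' Output has set semantics: a topic counts at most once per record, however
#' many variants or repetitions occur, matching per-record counting in the
#' topic-trend matrices. Annotation is monotone: adding text never removes a
#' topic.
#'
#' @param corpus A corpus tibble (or a single record row).
#' @param lexicon Topic lexicon tibble from [load_topic_lexicon()].
#' @return A tibble `record_id`, `panel`, `topic`, one row per detected
#'   record-topic pair.
#' @export
annotate_topics <- function(corpus, lexicon = load_topic_lexicon()) {
  lex <- lexicon %>% rename(canonical = "topic")
  out <- purrr::map(seq_len(nrow(corpus)), function(i) {
    rec <- corpus[i, ]
    text_fields <- c(rec$title, rec$keywords[[1]], rec$abstract)
    hits <- purrr::map(text_fields, ~ locate_lexicon(.x %||% "", lex)) %>% bind_rows()
    if (nrow(hits) == 0) return(NULL)
    tibble(record_id = rec$record_id, topic = unique(hits$canonical))
  }) %>%
    purrr::compact() %>%
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(record_id = character(), panel = character(), topic = character()))
  }
  out %>%
    left_join(distinct(lexicon, .data$panel, .data$topic), by = "topic") %>%
    select("record_id", "panel", "topic")
}
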