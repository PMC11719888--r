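#' @title Platform and tumor-model classification
#' @description
#' The staged rule engine that routes each record into the organoid /
#' tumor-organoid / organ-on-chip (OoC) / tumor-on-chip (ToC) corpora:
#'
#' 1. *Prefix rule*: an organ alias whose final token lies within the four
#'    tokens immediately preceding an organoid-class model term attaches to
#'    it; for on-chip terms the organ alias or organotypic-process name must
#'    immediately precede the on-chip suffix (hyphen- or space-joined).
#' 2. *Sentence rule* (only when the prefix rule finds nothing): organ
#'    aliases in any sentence containing a model term attach.
#'
#' Tumor status requires an oncological term in the matched context: within
#' a symmetric four-token window around the organ-model span for prefix
#' matches, or in the same sentence for sentence-rule matches; terms that are
#' intrinsically oncological (tumoroid/tumouroid) set the flag directly.
#' Attached organs are retained as *tumor* organs only when an oncological
#' term co-occurs with that organ alias somewhere in the title, keywords or
#' abstract (four-token window or same sentence).
#' @name model_classifier
NULL

# The searchable fields of one record, each with its own sentence table.
record_fields <- function(record) {
  kw <- record$keywords[[1]] %||% character()
  kw_fields <- if (length(kw) > 0) {
    setNames(as.list(kw), paste0("keyword_", seq_along(kw)))
  } else {
    list()
  }
  fields <- c(
    list(title = record$title %||% ""),
    kw_fields,
    list(abstract = record$abstract %||% "")
  )
  purrr::imap(fields, function(text, name) {
    sent <- if (stringr::str_starts(name, "abstract")) {
      split_sentences(text)
    } else if (nzchar(text %||% "")) {
      tibble(sentence = text, start = 1L, end = nchar(text))
    } else {
      tibble(sentence = character(), start = integer(), end = integer())
    }
    list(name = name, text = text %||% "", tokens = tokenize_text(text %||% ""), sentences = sent)
  })
}

match_token_span <- function(tokens, start, end) {
  if (nrow(tokens) == 0) return(c(NA_integer_, NA_integer_))
  first <- findInterval(start, tokens$start)
  last <- findInterval(end, tokens$start)
  c(max(first, 1L), max(last, 1L))
}

sentence_of <- function(sentences, offset) {
  if (nrow(sentences) == 0) return(NA_integer_)
  idx <- which(sentences$start <= offset & offset <= sentences$end)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Locate platform model-term mentions in a record
#'
#' Every occurrence of a model-lexicon surface variant in the title, keywords
#' or abstract is reported with its canonical term, term class (`organoid`,
#' `onchip`, `mps`), field and character offsets. Matching is
#' case-insensitive and hyphen/space tolerant. Terms with a `requires`
#' co-occurrence condition (the blastoid search requires "embryonic") only
#' count when the condition word occurs anywhere in the record.
#'
#' @param record One corpus row.
#' @param lexicons Lexicon list from [load_lexicons()].
#' @return A tibble: `field`, `canonical`, `class`, `variant`, `start`,
#'   `end`, `oncological`, `never_tumor`.
#' @export
find_model_terms <- function(record, lexicons = load_lexicons()) {
  lex <- lexicons$model_terms
  fields <- record_fields(record)
  all_text <- stringr::str_to_lower(paste(
    purrr::map_chr(fields, "text"),
    collapse = " "
  ))
  required <- unique(lex$requires[!is.na(lex$requires)])
  unmet <- required[!stringr::str_detect(all_text, stringr::fixed(required))]
  lex_use <- lex %>% filter(is.na(.data$requires) | !(.data$requires %in% unmet))
  purrr::map(fields, function(f) {
    hits <- locate_lexicon(f$text, lex_use)
    if (nrow(hits) == 0) return(NULL)
    hits %>%
      left_join(
        lex_use %>% distinct(.data$canonical, .data$class, .data$oncological, .data$never_tumor),
        by = "canonical"
      ) %>%
      mutate(field = f$name)
  }) %>%
    purrr::compact() %>%
    bind_rows() %>%
    (function(x) if (nrow(x) == 0) {
      tibble(
        field = character(), canonical = character(), class = character(),
        variant = character(), start = integer(), end = integer(),
        oncological = logical(), never_tumor = logical()
      )
    } else {
      x %>% select("field", "canonical", "class", "variant", "start", "end",
        "oncological", "never_tumor")
    })
}

# Organ/process alias table used by the classifier: node/process canonical +
# surface variant. Processes only attach to on-chip suffixes.
organ_alias_table <- function(taxonomy, lexicons) {
  bind_rows(
    taxonomy$aliases %>% mutate(is_process = FALSE),
    lexicons$organotypic_processes %>%
      rename(canonical = "canonical") %>%
      mutate(is_process = TRUE)
  )
}

#' Classify one record: platform, organs, tumor status, corpora
#'
#' Runs the staged proximity rules, assigns tumor status from the oncological
#' lexicon and routes the record to its corpora. See the module description
#' above for the rules.
#'
#' @param record One corpus row.
#' @param lexicons Lexicon list from [load_lexicons()].
#' @param taxonomy Taxonomy from [load_taxonomy()].
#' @return A one-row assignment tibble: `record_id`, `platform` (`organoid`,
#'   `ooc`, `both`, `none`), `tumor`, `detection_method` (`prefix`,
#'   `same_sentence`, `none`), `organ_aliases` (list-column of canonical
#'   organ/process terms), `corpora` (list-column, subset of `organoid`,
#'   `tumor_organoid`, `ooc`, `toc`), `overridden`.
#' @export
classify_record <- function(record, lexicons = load_lexicons(),
                            taxonomy = load_taxonomy()) {
  fields <- record_fields(record)
  alias_tab <- organ_alias_table(taxonomy, lexicons)
  onco_lex <- lexicons$oncological_terms
  model <- find_model_terms(record, lexicons)

  per_field <- purrr::map(fields, function(f) {
    list(
      f = f,
      organs = locate_lexicon(f$text, alias_tab) %>%
        left_join(distinct(alias_tab, .data$canonical, .data$is_process), by = "canonical"),
      onco = locate_lexicon(f$text, onco_lex),
      model = model %>% filter(.data$field == f$name)
    )
  })

  # ---- stage 1: prefix rule -------------------------------------------------
  attach <- list() # each: canonical, field, span_start_tok, span_end_tok, field tokens
  for (pf in per_field) {
    if (nrow(pf$model) == 0 || nrow(pf$organs) == 0) next
    toks <- pf$f$tokens
    for (i in seq_len(nrow(pf$model))) {
      m <- pf$model[i, ]
      mspan <- match_token_span(toks, m$start, m$end)
      for (j in seq_len(nrow(pf$organs))) {
        o <- pf$organs[j, ]
        if (m$class == "onchip") {
          # alias/process immediately precedes the suffix, '-' or ' ' joined
          sep <- stringr::str_sub(pf$f$text, o$end + 1, m$start - 1)
          if (o$end == m$start - 2 && sep %in% c("-", " ")) {
            ospan <- match_token_span(toks, o$start, o$end)
            attach[[length(attach) + 1L]] <- list(
              canonical = o$canonical, field = pf$f$name,
              span = c(ospan[1], mspan[2]), sentence = NA_integer_
            )
          }
        } else if (!o$is_process) {
          ospan <- match_token_span(toks, o$start, o$end)
          dist <- mspan[1] - ospan[2]
          if (!is.na(dist) && dist >= 1 && dist <= 4) {
            attach[[length(attach) + 1L]] <- list(
              canonical = o$canonical, field = pf$f$name,
              span = c(ospan[1], mspan[2]), sentence = NA_integer_
            )
          }
        }
      }
    }
  }
  method <- if (length(attach) > 0) "prefix" else "none"

  # ---- stage 2: sentence rule (only if stage 1 found nothing) ---------------
  if (method == "none") {
    for (pf in per_field) {
      if (nrow(pf$model) == 0 || nrow(pf$organs) == 0) next
      model_sents <- unique(purrr::map_int(pf$model$start, ~ sentence_of(pf$f$sentences, .x)))
      for (j in seq_len(nrow(pf$organs))) {
        o <- pf$organs[j, ]
        if (o$is_process) next
        osent <- sentence_of(pf$f$sentences, o$start)
        if (!is.na(osent) && osent %in% model_sents) {
          attach[[length(attach) + 1L]] <- list(
            canonical = o$canonical, field = pf$f$name,
            span = match_token_span(pf$f$tokens, o$start, o$end), sentence = osent
          )
        }
      }
    }
    if (length(attach) > 0) method <- "same_sentence"
  }

  # ---- platform -------------------------------------------------------------
  classes <- unique(model$class)
  has_organoid <- "organoid" %in% classes
  has_ooc <- any(c("onchip", "mps") %in% classes)
  platform <- if (has_organoid && has_ooc) "both"
  else if (has_organoid) "organoid"
  else if (has_ooc) "ooc"
  else "none"
  if (platform == "none") method <- "none"

  # ---- tumor status ---------------------------------------------------------
  tumor <- FALSE
  non_blastoid <- model %>% filter(!.data$never_tumor)
  if (nrow(non_blastoid) > 0) {
    if (any(non_blastoid$oncological)) tumor <- TRUE
    if (!tumor) {
      for (pf in per_field) {
        if (tumor) break
        if (nrow(pf$onco) == 0) next
        toks <- pf$f$tokens
        onco_spans <- purrr::map(seq_len(nrow(pf$onco)), function(k) {
          match_token_span(toks, pf$onco$start[k], pf$onco$end[k])
        })
        field_attach <- purrr::keep(attach, ~ .x$field == pf$f$name)
        if (method == "prefix" || method == "none") {
          # windows: +/- 4 tokens around each organ-model span (or the bare
          # model-term span when no organ attached)
          spans <- purrr::map(field_attach, "span")
          if (length(spans) == 0) {
            mm <- pf$model %>% filter(!.data$never_tumor)
            spans <- purrr::map(seq_len(nrow(mm)), function(k) {
              match_token_span(toks, mm$start[k], mm$end[k])
            })
          }
          for (sp in spans) {
            lo <- sp[1] - 4L; hi <- sp[2] + 4L
            if (any(purrr::map_lgl(onco_spans, ~ .x[2] >= lo && .x[1] <= hi))) {
              tumor <- TRUE
              break
            }
          }
        } else {
          # sentence-stage: oncological term in the matched sentence
          osents <- purrr::map_int(pf$onco$start, ~ sentence_of(pf$f$sentences, .x))
          msents <- purrr::map_int(field_attach, ~ .x$sentence %||% NA_integer_)
          if (length(msents) > 0 && any(osents %in% msents[!is.na(msents)])) tumor <- TRUE
        }
      }
    }
  }

  organs <- unique(purrr::map_chr(attach, "canonical"))

  # ---- tumor-organ retention ------------------------------------------------
  # an attached organ is a *tumor* organ only if an oncological term co-occurs
  # with an occurrence of that organ alias anywhere in the record
  if (tumor && length(organs) > 0) {
    keep <- purrr::map_lgl(organs, function(canon) {
      for (pf in per_field) {
        occ <- pf$organs %>% filter(.data$canonical == canon)
        if (nrow(occ) == 0 || nrow(pf$onco) == 0) next
        toks <- pf$f$tokens
        for (k in seq_len(nrow(occ))) {
          ospan <- match_token_span(toks, occ$start[k], occ$end[k])
          osent <- sentence_of(pf$f$sentences, occ$start[k])
          for (q in seq_len(nrow(pf$onco))) {
            cspan <- match_token_span(toks, pf$onco$start[q], pf$onco$end[q])
            if (cspan[2] >= ospan[1] - 4L && cspan[1] <= ospan[2] + 4L) return(TRUE)
            csent <- sentence_of(pf$f$sentences, pf$onco$start[q])
            if (!is.na(csent) && !is.na(osent) && csent == osent) return(TRUE)
          }
        }
      }
      FALSE
    })
    organs <- organs[keep]
  }

  corpora <- route_corpora(platform, tumor)
  tibble(
    record_id = record$record_id,
    platform = platform,
    tumor = tumor,
    detection_method = method,
    organ_aliases = list(organs),
    corpora = list(corpora),
    overridden = FALSE
  )
}

#' Route a classified record to its corpora
#'
#' Organoid-platform records go to the organoid corpus (plus tumor_organoid
#' when the tumor flag is set); on-chip and microphysiological-system records
#' go to the integrated OoC corpus (plus ToC when tumor). Dual-platform
#' records carry both lineages.
#'
#' @param platform `"organoid"`, `"ooc"`, `"both"` or `"none"`.
#' @param tumor Logical tumor flag.
#' @return Character vector, subset of
#'   `c("organoid", "tumor_organoid", "ooc", "toc")`.
#' @export
route_corpora <- function(platform, tumor) {
  out <- character()
  if (platform %in% c("organoid", "both")) {
    out <- c(out, "organoid", if (tumor) "tumor_organoid")
  }
  if (platform %in% c("ooc", "both")) {
    out <- c(out, "ooc", if (tumor) "toc")
  }
  out
}

#' Classify every record of a corpus
#'
#' @param corpus A corpus tibble.
#' @param lexicons,taxonomy Configuration objects; shipped defaults if omitted.
#' @param overrides Optional override table (see [apply_overrides()]).
#' @return An assignment tibble, one row per record (see [classify_record()]).
#' @export
classify_corpus <- function(corpus, lexicons = load_lexicons(),
                            taxonomy = load_taxonomy(), overrides = NULL) {
  if (nrow(corpus) == 0) {
    out <- tibble(
      record_id = character(), platform = character(), tumor = logical(),
      detection_method = character(), organ_aliases = list(),
      corpora = list(), overridden = logical()
    )
  } else {
    out <- purrr::map(seq_len(nrow(corpus)), function(i) {
      classify_record(corpus[i, ], lexicons, taxonomy)
    }) %>% bind_rows()
  }
  if (!is.null(overrides)) out <- apply_overrides(out, overrides)
  out
}

#' Apply manual curation overrides to assignments
#'
#' Mirrors the manual-adjustment step for infrequently studied organ
#' representations: overridden records carry the forced organ aliases (and,
#' optionally, corpora) and are flagged; all other records are untouched.
#'
#' @param assignments Assignment tibble from [classify_corpus()].
#' @param override_table Tibble with `record_id` and `organs` (list-column or
#'   `;`-separated string), optionally `corpora` in the same form.
#' @return The patched assignment tibble.
#' @export
apply_overrides <- function(assignments, override_table) {
  if (is.null(override_table) || nrow(override_table) == 0) return(assignments)
  unknown <- setdiff(override_table$record_id, assignments$record_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "override table references unknown record id(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  as_list_col <- function(x) {
    if (is.list(x)) x else stringr::str_split(x, ";\\s*")
  }
  organs <- as_list_col(override_table$organs)
  corpora <- if ("corpora" %in% names(override_table)) {
    as_list_col(override_table$corpora)
  } else {
    NULL
  }
  for (i in seq_len(nrow(override_table))) {
    j <- which(assignments$record_id == override_table$record_id[i])
    assignments$organ_aliases[[j]] <- organs[[i]]
    if (!is.null(corpora)) assignments$corpora[[j]] <- corpora[[i]]
    assignments$overridden[j] <- TRUE
  }
  assignments
}
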