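# Independent brute-force evaluators used as oracles. Deliberately written
# in plain base R with exhaustive loops, not sharing code with the package.

oracle_variant_matches <- function(text, variants_df) {
  empty <- data.frame(canonical = character(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(text) || nrow(variants_df) == 0) return(empty)
  tl <- tolower(text)
  cand <- list()
  for (i in seq_len(nrow(variants_df))) {
    v <- tolower(variants_df$variant[i])
    esc <- gsub("([][{}()+*^$|?.\\\\])", "\\\\\\1", v, perl = TRUE)
    pat <- paste0("(?<![a-z0-9])", gsub("[- ]+", "[- ]", esc), "(?![a-z0-9])")
    m <- gregexpr(pat, tl, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      cand[[length(cand) + 1]] <- data.frame(
        canonical = variants_df$canonical[i],
        start = as.integer(m[k]),
        end = as.integer(m[k] + attr(m, "match.length")[k] - 1)
      )
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  taken <- rep(FALSE, nchar(text))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

oracle_tokens <- function(text) {
  m <- gregexpr("[a-z0-9][a-z0-9-]*", tolower(text), perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m), end = as.integer(m + attr(m, "match.length") - 1))
}

oracle_token_index <- function(tokens, pos) {
  idx <- which(tokens$start <= pos)
  if (length(idx) == 0) 1L else max(idx)
}

# plain sentence split: boundary at ./!/? followed by whitespace (fixture and
# synthetic texts contain no abbreviations)
oracle_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- gregexpr("[.!?](?=\\s)", text, perl = TRUE)[[1]]
  breaks <- if (m[1] == -1) integer() else as.integer(m)
  starts <- 1L
  rows <- list()
  for (b in breaks) {
    rows[[length(rows) + 1]] <- c(starts, b)
    nxt <- b + 1L
    while (nxt <= nchar(text) && grepl("^\\s$", substr(text, nxt, nxt))) nxt <- nxt + 1L
    starts <- nxt
  }
  if (starts <= nchar(text)) rows[[length(rows) + 1]] <- c(starts, nchar(text))
  out <- do.call(rbind, rows)
  data.frame(start = out[, 1], end = out[, 2])
}

oracle_sentence_of <- function(sent, pos) {
  for (i in seq_len(nrow(sent))) {
    if (sent$start[i] <= pos && pos <= sent$end[i]) return(i)
  }
  NA_integer_
}

# full reimplementation of the staged rules, exhaustive over token windows
# and sentences
oracle_classify <- function(record, lexicons, taxonomy) {
  model_lex <- lexicons$model_terms
  onco_lex <- lexicons$oncological_terms
  organ_lex <- rbind(
    data.frame(
      canonical = taxonomy$aliases$canonical,
      variant = taxonomy$aliases$variant, is_process = FALSE
    ),
    data.frame(
      canonical = lexicons$organotypic_processes$canonical,
      variant = lexicons$organotypic_processes$variant, is_process = TRUE
    )
  )
  fields <- c(list(record$title), as.list(record$keywords[[1]]), list(record$abstract))
  fields <- lapply(fields, function(x) if (is.na(x)) "" else x)
  all_text <- tolower(paste(unlist(fields), collapse = " "))

  meta <- unique(model_lex[, c("canonical", "class", "oncological", "never_tumor", "requires")])
  usable <- is.na(meta$requires) | vapply(
    meta$requires, function(r) grepl(r, all_text, fixed = TRUE), logical(1)
  )
  model_lex <- model_lex[model_lex$canonical %in% meta$canonical[usable], ]

  per_field <- lapply(fields, function(txt) {
    mm <- oracle_variant_matches(txt, model_lex[, c("canonical", "variant")])
    if (nrow(mm) > 0) {
      mm <- merge(mm, meta[, c("canonical", "class", "oncological", "never_tumor")],
        by = "canonical", sort = FALSE)
      mm <- mm[order(mm$start), , drop = FALSE]
    } else {
      mm$class <- character(); mm$oncological <- logical(); mm$never_tumor <- logical()
    }
    oo <- oracle_variant_matches(txt, organ_lex[, c("canonical", "variant")])
    oo$is_process <- organ_lex$is_process[match(oo$canonical, organ_lex$canonical)]
    list(
      text = txt, tokens = oracle_tokens(txt), sents = oracle_sentences(txt),
      model = mm, organs = oo,
      onco = oracle_variant_matches(txt, onco_lex)
    )
  })

  # stage 1: exhaustive prefix scan
  attach <- list()
  for (pf in per_field) {
    for (i in seq_len(nrow(pf$model))) {
      m_first <- oracle_token_index(pf$tokens, pf$model$start[i])
      m_last <- oracle_token_index(pf$tokens, pf$model$end[i])
      for (j in seq_len(nrow(pf$organs))) {
        o_last <- oracle_token_index(pf$tokens, pf$organs$end[j])
        o_first <- oracle_token_index(pf$tokens, pf$organs$start[j])
        hit <- FALSE
        if (pf$model$class[i] == "onchip") {
          gap <- substr(pf$text, pf$organs$end[j] + 1, pf$model$start[i] - 1)
          hit <- (pf$organs$end[j] == pf$model$start[i] - 2) && gap %in% c("-", " ")
        } else if (!pf$organs$is_process[j]) {
          d <- m_first - o_last
          hit <- d >= 1 && d <= 4
        }
        if (hit) {
          attach[[length(attach) + 1]] <- list(
            canonical = pf$organs$canonical[j], pf = pf,
            span = c(o_first, m_last), sent = NA_integer_
          )
        }
      }
    }
  }
  method <- if (length(attach) > 0) "prefix" else "none"
  if (method == "none") {
    for (pf in per_field) {
      if (nrow(pf$model) == 0) next
      msents <- unique(vapply(
        pf$model$start, function(p) oracle_sentence_of(pf$sents, p), integer(1)
      ))
      for (j in seq_len(nrow(pf$organs))) {
        if (pf$organs$is_process[j]) next
        os <- oracle_sentence_of(pf$sents, pf$organs$start[j])
        if (!is.na(os) && os %in% msents) {
          attach[[length(attach) + 1]] <- list(
            canonical = pf$organs$canonical[j], pf = pf,
            span = c(
              oracle_token_index(pf$tokens, pf$organs$start[j]),
              oracle_token_index(pf$tokens, pf$organs$end[j])
            ),
            sent = os
          )
        }
      }
    }
    if (length(attach) > 0) method <- "same_sentence"
  }

  classes <- unique(unlist(lapply(per_field, function(pf) pf$model$class)))
  platform <- if (all(c("organoid") %in% classes) && any(c("onchip", "mps") %in% classes)) {
    "both"
  } else if ("organoid" %in% classes) {
    "organoid"
  } else if (any(c("onchip", "mps") %in% classes)) "ooc" else "none"
  if (platform == "none") method <- "none"

  tumor <- FALSE
  any_non_blastoid <- any(unlist(lapply(per_field, function(pf) !pf$model$never_tumor)))
  if (isTRUE(any_non_blastoid)) {
    if (any(unlist(lapply(per_field, function(pf) {
      pf$model$oncological & !pf$model$never_tumor
    })))) {
      tumor <- TRUE
    }
    if (!tumor) {
      for (pf in per_field) {
        if (nrow(pf$onco) == 0) next
        if (method %in% c("prefix", "none")) {
          spans <- lapply(Filter(function(a) identical(a$pf$text, pf$text), attach), `[[`, "span")
          if (length(spans) == 0) {
            mm <- pf$model[!pf$model$never_tumor, , drop = FALSE]
            spans <- lapply(seq_len(nrow(mm)), function(i) {
              c(
                oracle_token_index(pf$tokens, mm$start[i]),
                oracle_token_index(pf$tokens, mm$end[i])
              )
            })
          }
          for (sp in spans) {
            for (q in seq_len(nrow(pf$onco))) {
              c1 <- oracle_token_index(pf$tokens, pf$onco$start[q])
              c2 <- oracle_token_index(pf$tokens, pf$onco$end[q])
              if (c2 >= sp[1] - 4 && c1 <= sp[2] + 4) tumor <- TRUE
            }
          }
        } else {
          sents <- vapply(
            Filter(function(a) identical(a$pf$text, pf$text), attach),
            function(a) a$sent, integer(1)
          )
          for (q in seq_len(nrow(pf$onco))) {
            if (oracle_sentence_of(pf$sents, pf$onco$start[q]) %in% sents) tumor <- TRUE
          }
        }
      }
    }
  }

  organs <- unique(vapply(attach, function(a) a$canonical, character(1)))
  if (tumor && length(organs) > 0) {
    keep <- vapply(organs, function(canon) {
      for (pf in per_field) {
        occ <- pf$organs[pf$organs$canonical == canon, , drop = FALSE]
        if (nrow(occ) == 0 || nrow(pf$onco) == 0) next
        for (k in seq_len(nrow(occ))) {
          o1 <- oracle_token_index(pf$tokens, occ$start[k])
          o2 <- oracle_token_index(pf$tokens, occ$end[k])
          os <- oracle_sentence_of(pf$sents, occ$start[k])
          for (q in seq_len(nrow(pf$onco))) {
            c1 <- oracle_token_index(pf$tokens, pf$onco$start[q])
            c2 <- oracle_token_index(pf$tokens, pf$onco$end[q])
            if (c2 >= o1 - 4 && c1 <= o2 + 4) return(TRUE)
            cs <- oracle_sentence_of(pf$sents, pf$onco$start[q])
            if (!is.na(cs) && !is.na(os) && cs == os) return(TRUE)
          }
        }
      }
      FALSE
    }, logical(1))
    organs <- organs[keep]
  }

  corp <- character()
  if (platform %in% c("organoid", "both")) corp <- c(corp, "organoid", if (tumor) "tumor_organoid")
  if (platform %in% c("ooc", "both")) corp <- c(corp, "ooc", if (tumor) "toc")
  list(
    platform = platform, tumor = tumor, method = method,
    organs = sort(organs), corpora = sort(corp)
  )
}

# brute-force pairwise duplicate matcher (doi first, else normalized title;
# distinct non-empty dois never match)
oracle_match_count <- function(old, new) {
  norm_title <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    trimws(gsub(" +", " ", x))
  }
  n <- 0L
  for (i in seq_len(nrow(new))) {
    matched <- FALSE
    for (j in seq_len(nrow(old))) {
      if (!is.na(new$doi[i]) && !is.na(old$doi[j]) && new$doi[i] == old$doi[j]) {
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      for (j in seq_len(nrow(old))) {
        if (is.na(new$doi[i]) || is.na(old$doi[j])) {
          if (norm_title(new$title[i]) == norm_title(old$title[j])) {
            matched <- TRUE
            break
          }
        }
      }
    }
    if (matched) n <- n + 1L
  }
  n
}
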