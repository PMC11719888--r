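#' @title Corpus ingestion: reference-manager metadata to normalized records
#' @description
#' Publication metadata arrives as RIS (EMBASE), PubMed nbib, or BibTeX
#' (Scopus / Web of Science / bioRxiv) exports. `parse_metadata_file()` maps
#' each entry onto one normalized record, applies [normalize_text()] to every
#' text field and rejects (with a warning) entries lacking a publication year.
#'
#' A corpus is a plain tibble, one record per row, with columns `record_id`,
#' `source_db`, `native_id`, `doi`, `title`, `abstract`, `keywords`
#' (list-column), `affiliation_text`, `year`, `doc_type`.
#' @name corpus_io
NULL

corpus_columns <- c(
  "record_id", "source_db", "native_id", "doi", "title", "abstract",
  "keywords", "affiliation_text", "year", "doc_type"
)

empty_corpus <- function() {
  tibble(
    record_id = character(), source_db = character(), native_id = character(),
    doi = character(), title = character(), abstract = character(),
    keywords = list(), affiliation_text = character(), year = integer(),
    doc_type = character()
  )
}

# Document-type normalization: databases label comments, editorials, retracted
# articles and retraction notices, which are excluded downstream.
normalize_doc_type <- function(x) {
  x <- stringr::str_to_lower(stringr::str_trim(x %||% ""))
  excluded <- c(
    "comment", "editorial", "retracted article", "retracted publication",
    "retraction notice", "retraction of publication", "erratum", "letter",
    "news"
  )
  dplyr::case_when(
    x %in% c("review", "systematic review") ~ "review",
    x %in% c("preprint") ~ "preprint",
    x %in% excluded ~ "excluded_type",
    TRUE ~ "article"
  )
}

default_source_for_dialect <- c(ris = "embase", nbib = "pubmed", bib = "scopus")

#' Parse a reference-manager metadata file into a corpus
#'
#' @param path File path.
#' @param dialect One of `"auto"` (by extension), `"ris"`, `"nbib"`, `"bib"`.
#' @param source_db Origin label (`embase`, `pubmed`, `scopus`, `wos`,
#'   `biorxiv`, `synthetic`); defaults by dialect (ris = embase,
#'   nbib = pubmed, bib = scopus).
#' @param acquisition_tag Free-text label for the pull (e.g. `"initial"` or
#'   `"update"`), stored in the `acquisition` attribute.
#' @return A corpus tibble (one row per parsed record). Entries without a
#'   recoverable year are dropped with a warning naming how many.
#' @export
parse_metadata_file <- function(path, dialect = c("auto", "ris", "nbib", "bib"),
                                source_db = NULL, acquisition_tag = "initial") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("cannot read metadata file '%s'", path))
  if (dialect == "auto") {
    ext <- stringr::str_to_lower(tools::file_ext(path))
    dialect <- switch(ext,
      ris = "ris", nbib = "nbib", bib = "bib", bibtex = "bib",
      abort(sprintf("cannot infer dialect from extension '.%s'", ext))
    )
  }
  source_db <- source_db %||% unname(default_source_for_dialect[dialect])
  raw <- readChar(path, file.info(path)$size, useBytes = FALSE)
  Encoding(raw) <- "UTF-8"
  entries <- switch(dialect,
    ris = parse_ris_text(raw),
    nbib = parse_nbib_text(raw),
    bib = parse_bib_text(raw)
  )
  records <- entries_to_corpus(entries, source_db)
  attr(records, "acquisition") <- acquisition_tag
  records
}

# Common path: list of per-entry field lists -> corpus tibble.
entries_to_corpus <- function(entries, source_db) {
  if (length(entries) == 0) return(empty_corpus())
  rows <- purrr::map(entries, function(e) {
    yr <- suppressWarnings(as.integer(stringr::str_extract(e$year %||% "", "\\d{4}")))
    tibble(
      source_db = e$source_db %||% source_db,
      native_id = normalize_text(e$native_id %||% NA_character_),
      doi = normalize_doi(normalize_text(e$doi %||% NA_character_)),
      title = normalize_text(e$title %||% ""),
      abstract = normalize_text(e$abstract %||% ""),
      keywords = list(normalize_text(e$keywords %||% character())),
      affiliation_text = normalize_text(paste(e$affiliations %||% character(), collapse = "; ")),
      year = yr,
      doc_type = normalize_doc_type(e$doc_type %||% "article")
    )
  })
  out <- bind_rows(rows)
  no_year <- is.na(out$year)
  if (any(no_year)) {
    warn(sprintf(
      "%d record(s) without a publication year were rejected: %s",
      sum(no_year),
      paste(utils::head(out$title[no_year], 3), collapse = "; ")
    ))
    out <- out[!no_year, ]
  }
  if (nrow(out) == 0) return(empty_corpus())
  out$record_id <- make_record_id(out$source_db, out$native_id, out$title, out$year)
  out[, corpus_columns]
}

## ---- RIS ------------------------------------------------------------------

# Explicit RIS tag map; unmapped tags are ignored.
ris_tag_map <- c(
  TY = "type", TI = "title", T1 = "title", AB = "abstract", N2 = "abstract",
  KW = "keyword", AD = "affiliation", PY = "year", Y1 = "year",
  DO = "doi", AN = "native_id", ID = "native_id", M3 = "subtype", DB = "source"
)

parse_ris_text <- function(raw) {
  lines <- stringr::str_split(raw, "\r?\n")[[1]]
  entries <- list()
  cur <- NULL
  cur_tag <- NULL
  flush_entry <- function(cur) {
    if (is.null(cur)) return(NULL)
    doc_type <- cur$subtype %||% (if (identical(cur$type, "JOUR")) "article" else cur$type)
    list(
      title = paste(cur$title, collapse = " "),
      abstract = paste(cur$abstract, collapse = " "),
      keywords = cur$keyword, affiliations = cur$affiliation,
      year = cur$year[1], doi = cur$doi[1], native_id = cur$native_id[1],
      doc_type = doc_type, source_db = cur$source[1]
    )
  }
  for (line in lines) {
    m <- stringr::str_match(line, "^([A-Z][A-Z0-9])  - ?(.*)$")
    if (!is.na(m[1, 1])) {
      tag <- m[1, 2]; val <- stringr::str_trim(m[1, 3])
      if (tag == "ER") {
        e <- flush_entry(cur)
        if (!is.null(e)) entries[[length(entries) + 1L]] <- e
        cur <- NULL; cur_tag <- NULL
        next
      }
      if (is.null(cur)) cur <- list()
      field <- ris_tag_map[tag]
      if (is.na(field)) { cur_tag <- NULL; next }
      if (field == "subtype") field <- "subtype"
      cur[[field]] <- c(cur[[field]], val)
      cur_tag <- field
    } else if (!is.null(cur) && !is.null(cur_tag) && nzchar(stringr::str_trim(line))) {
      # continuation line: append to the last value of the open tag
      n <- length(cur[[cur_tag]])
      cur[[cur_tag]][n] <- paste(cur[[cur_tag]][n], stringr::str_trim(line))
    }
  }
  # tolerate a final entry missing its ER terminator
  e <- flush_entry(cur)
  if (!is.null(e)) {
    warn("RIS entry without 'ER' terminator at end of file; parsed anyway")
    entries[[length(entries) + 1L]] <- e
  }
  entries
}

## ---- PubMed nbib ----------------------------------------------------------

nbib_tag_map <- c(
  PMID = "native_id", TI = "title", AB = "abstract", OT = "keyword",
  MH = "keyword", AD = "affiliation", DP = "year", PT = "doc_types",
  LID = "lid", AID = "lid", SO = "ignore"
)

parse_nbib_text <- function(raw) {
  lines <- stringr::str_split(raw, "\r?\n")[[1]]
  entries <- list()
  cur <- NULL
  cur_tag <- NULL
  flush_entry <- function(cur) {
    if (is.null(cur) || length(cur) == 0) return(NULL)
    types <- stringr::str_to_lower(cur$doc_types %||% character())
    doc_type <- if (any(stringr::str_detect(types, "retract"))) {
      "retracted article"
    } else if ("comment" %in% types) "comment"
    else if ("editorial" %in% types) "editorial"
    else if ("review" %in% types) "review"
    else if ("preprint" %in% types) "preprint"
    else "article"
    doi <- NA_character_
    lid <- cur$lid %||% character()
    hit <- stringr::str_match(lid, "^(\\S+) \\[doi\\]")[, 2]
    if (any(!is.na(hit))) doi <- hit[!is.na(hit)][1]
    list(
      title = paste(cur$title, collapse = " "),
      abstract = paste(cur$abstract, collapse = " "),
      keywords = cur$keyword, affiliations = cur$affiliation,
      year = cur$year[1], doi = doi, native_id = cur$native_id[1],
      doc_type = doc_type
    )
  }
  for (line in lines) {
    if (!nzchar(stringr::str_trim(line))) next
    m <- stringr::str_match(line, "^([A-Z]{1,4}[A-Z0-9]?) *- ?(.*)$")
    if (!is.na(m[1, 1])) {
      tag <- m[1, 2]; val <- stringr::str_trim(m[1, 3])
      if (tag == "PMID" && !is.null(cur)) {
        e <- flush_entry(cur)
        if (!is.null(e)) entries[[length(entries) + 1L]] <- e
        cur <- NULL
      }
      if (is.null(cur)) cur <- list()
      field <- nbib_tag_map[tag]
      if (is.na(field) || field == "ignore") { cur_tag <- NULL; next }
      cur[[field]] <- c(cur[[field]], val)
      cur_tag <- field
    } else if (!is.null(cur) && !is.null(cur_tag) && stringr::str_detect(line, "^\\s+")) {
      n <- length(cur[[cur_tag]])
      cur[[cur_tag]][n] <- paste(cur[[cur_tag]][n], stringr::str_trim(line))
    }
  }
  e <- flush_entry(cur)
  if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  entries
}

## ---- BibTeX ---------------------------------------------------------------

parse_bib_text <- function(raw) {
  entries <- list()
  starts <- stringr::str_locate_all(raw, "@[A-Za-z]+\\s*\\{")[[1]]
  if (nrow(starts) == 0) return(entries)
  for (i in seq_len(nrow(starts))) {
    open <- starts[i, 2]
    etype <- stringr::str_to_lower(
      stringr::str_remove_all(stringr::str_sub(raw, starts[i, 1] + 1, open - 1), "[\\s{]")
    )
    # brace-count to the matching close
    depth <- 1L
    pos <- open
    nmax <- nchar(raw)
    while (depth > 0 && pos < nmax) {
      pos <- pos + 1L
      ch <- stringr::str_sub(raw, pos, pos)
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") depth <- depth - 1L
    }
    body <- stringr::str_sub(raw, open + 1, pos - 1)
    key <- stringr::str_match(body, "^\\s*([^,\\s]+)\\s*,")[, 2]
    fields <- parse_bib_fields(body)
    doc_type <- fields[["document_type"]] %||% fields[["type"]] %||%
      switch(etype, article = "article", unpublished = "preprint", misc = "preprint", etype)
    kw <- fields[["keywords"]] %||% fields[["keyword"]] %||% ""
    keywords <- stringr::str_trim(stringr::str_split(kw, ";")[[1]])
    keywords <- keywords[nzchar(keywords)]
    entries[[length(entries) + 1L]] <- list(
      title = fields[["title"]] %||% "",
      abstract = fields[["abstract"]] %||% "",
      keywords = keywords,
      affiliations = fields[["affiliation"]] %||% fields[["address"]] %||% character(),
      year = fields[["year"]], doi = fields[["doi"]],
      native_id = key, doc_type = doc_type,
      source_db = fields[["source"]]
    )
  }
  entries
}

parse_bib_fields <- function(body) {
  fields <- list()
  m <- stringr::str_locate_all(body, "(?i)([a-z_]+)\\s*=\\s*[{\"]")[[1]]
  if (nrow(m) == 0) return(fields)
  for (i in seq_len(nrow(m))) {
    seg <- stringr::str_sub(body, m[i, 1], m[i, 2])
    name <- stringr::str_to_lower(stringr::str_match(seg, "([A-Za-z_]+)")[, 2])
    opener <- stringr::str_sub(body, m[i, 2], m[i, 2])
    pos <- m[i, 2]
    if (opener == "{") {
      depth <- 1L
      while (depth > 0 && pos < nchar(body)) {
        pos <- pos + 1L
        ch <- stringr::str_sub(body, pos, pos)
        if (ch == "{") depth <- depth + 1L
        if (ch == "}") depth <- depth - 1L
      }
      val <- stringr::str_sub(body, m[i, 2] + 1, pos - 1)
    } else {
      close <- stringr::str_locate(stringr::str_sub(body, m[i, 2] + 1), "\"")[1]
      val <- stringr::str_sub(body, m[i, 2] + 1, m[i, 2] + close - 1)
    }
    fields[[name]] <- stringr::str_squish(val)
  }
  fields
}

## ---- serializers (synthetic output and round-trip support) ----------------

#' Serialize a corpus back to a reference-manager dialect
#'
#' Writes the supported fields (title, abstract, keywords, affiliations,
#' year, doi, native id, document type) in the named dialect so that
#' parse -> serialize -> parse round-trips record content.
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @param dialect `"ris"`, `"nbib"` or `"bib"`.
#' @return `path`, invisibly.
#' @export
write_metadata_file <- function(corpus, path, dialect = c("ris", "nbib", "bib")) {
  dialect <- match.arg(dialect)
  lines <- switch(dialect,
    ris = purrr::pmap(corpus, function(record_id, source_db, native_id, doi, title,
                                       abstract, keywords, affiliation_text, year, doc_type) {
      c(
        "TY  - JOUR",
        paste0("M3  - ", doc_type_label(doc_type)),
        paste0("AN  - ", id_or(native_id, record_id)),
        paste0("TI  - ", title),
        if (nzchar(abstract)) paste0("AB  - ", abstract),
        purrr::map_chr(keywords, ~ paste0("KW  - ", .x)),
        if (nzchar(affiliation_text)) paste0("AD  - ", affiliation_text),
        paste0("PY  - ", year),
        if (!is.na(doi)) paste0("DO  - ", doi),
        "ER  - ", ""
      )
    }),
    nbib = purrr::pmap(corpus, function(record_id, source_db, native_id, doi, title,
                                        abstract, keywords, affiliation_text, year, doc_type) {
      c(
        paste0("PMID- ", stringr::str_remove(id_or(native_id, record_id), "^[a-z]+_")),
        paste0("TI  - ", title),
        if (nzchar(abstract)) paste0("AB  - ", abstract),
        purrr::map_chr(keywords, ~ paste0("OT  - ", .x)),
        if (nzchar(affiliation_text)) paste0("AD  - ", affiliation_text),
        paste0("DP  - ", year),
        paste0("PT  - ", doc_type_label(doc_type)),
        if (!is.na(doi)) paste0("LID - ", doi, " [doi]"),
        ""
      )
    }),
    bib = purrr::pmap(corpus, function(record_id, source_db, native_id, doi, title,
                                       abstract, keywords, affiliation_text, year, doc_type) {
      c(
        paste0("@article{", id_or(native_id, record_id), ","),
        paste0("  title = {", title, "},"),
        if (nzchar(abstract)) paste0("  abstract = {", abstract, "},"),
        if (length(keywords) > 0) paste0("  keywords = {", paste(keywords, collapse = "; "), "},"),
        if (nzchar(affiliation_text)) paste0("  affiliation = {", affiliation_text, "},"),
        paste0("  year = {", year, "},"),
        if (!is.na(doi)) paste0("  doi = {", doi, "},"),
        paste0("  document_type = {", doc_type_label(doc_type), "}"),
        "}", ""
      )
    })
  )
  writeLines(unlist(lines), path, useBytes = TRUE)
  invisible(path)
}

id_or <- function(a, b) if (is.na(a) || !nzchar(a)) b else a

doc_type_label <- function(doc_type) {
  c(
    article = "Journal Article", review = "Review", preprint = "Preprint",
    excluded_type = "Editorial"
  )[doc_type]
}

## ---- filters and flat exports ---------------------------------------------

#' Drop excluded document types from a corpus
#'
#' Removes records typed as comments, editorials, retracted articles or
#' retraction notices (normalized to `excluded_type` at parse time), keeping
#' articles, reviews and preprints in their original order. Idempotent and
#' never increases the record count.
#'
#' @param corpus A corpus tibble.
#' @return The filtered corpus tibble.
#' @export
filter_document_types <- function(corpus) {
  corpus %>% filter(.data$doc_type %in% c("article", "review", "preprint"))
}

#' Write / read a corpus as JSON lines
#'
#' One JSON object per record, suitable for inspection and for chaining
#' pipeline stages through files.
#'
#' @param corpus A corpus tibble.
#' @param path File path (`.jsonl`).
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` returns
#'   the corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    row <- as.list(corpus[i, ])
    row$keywords <- row$keywords[[1]]
    jsonlite::toJSON(row, auto_unbox = TRUE, null = "null", na = "null")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_corpus())
  rows <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    kw <- x$keywords
    x$keywords <- NULL
    out <- as_tibble(purrr::map(x, ~ .x %||% NA))
    out$keywords <- list(as.character(kw %||% character()))
    out
  })
  out <- bind_rows(rows)
  out$year <- as.integer(out$year)
  out[, corpus_columns]
}
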