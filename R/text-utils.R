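#' Normalize typographic characters in metadata text
#'
#' Database exports carry typographic em dashes, en dashes and non-breaking
#' spaces that break downstream token matching. `normalize_text()` maps every
#' em dash (U+2014) and en dash (U+2013) to a plain hyphen-minus and every
#' non-breaking space (U+00A0) to a plain space. All other characters are
#' preserved, so the function is length-preserving and idempotent. It is a
#' total function: `NA` stays `NA`.
#'
#' @param raw Character vector.
#' @return Character vector of the same length with the replacements applied.
#' @examples
#' normalize_text("tumor–on–chip")
#' @export
normalize_text <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- stringr::str_replace_all(raw, "[–—]", "-")
  stringr::str_replace_all(out, " ", " ")
}

# Token = maximal run of letters/digits/hyphens after case-folding.
# Returns a tibble with token text and character start/end (1-based).
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  loc <- stringr::str_locate_all(text, "[A-Za-z0-9][A-Za-z0-9-]*")[[1]]
  tibble(
    token = stringr::str_to_lower(stringr::str_sub(text, loc[, 1], loc[, 2])),
    start = as.integer(loc[, 1]),
    end = as.integer(loc[, 2])
  )
}

# Abbreviations that never end a sentence (lower-case, without the final dot).
sentence_abbreviations <- c(
  "e.g", "i.e", "et al", "etc", "fig", "figs", "vs", "ca", "cf", "no",
  "approx", "resp", "dr", "prof", "spp", "sp"
)

#' Split text into sentences with character offsets
#'
#' Boundaries are placed after sentence-final punctuation (`.`, `!`, `?`)
#' followed by whitespace, except when the punctuation terminates a known
#' abbreviation (e.g., "e.g.", "et al.", "Fig."). The concatenation of the
#' returned sentence substrings (including their trailing separators)
#' reconstructs the input exactly.
#'
#' @param text A single character string (already normalized).
#' @return A tibble with columns `sentence`, `start`, `end` (character
#'   offsets of the sentence body, separators excluded from `sentence` but
#'   covered by the next `start`).
#' @export
split_sentences <- function(text) {
  empty <- tibble(sentence = character(), start = integer(), end = integer())
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    return(empty)
  }
  cand <- stringr::str_locate_all(text, "[.!?](?=\\s)")[[1]]
  breaks <- integer()
  for (pos in cand[, 1]) {
    prefix <- stringr::str_sub(text, 1, pos - 1)
    word <- stringr::str_to_lower(
      stringr::str_extract(prefix, "[A-Za-z][A-Za-z.]*$") %||% ""
    )
    if (is.na(word)) word <- ""
    # last one or two words before the dot, checked against abbreviation list
    two <- stringr::str_to_lower(
      stringr::str_extract(prefix, "[A-Za-z]+ [A-Za-z]+$") %||% ""
    )
    if (is.na(two)) two <- ""
    if (word %in% sentence_abbreviations || two %in% sentence_abbreviations) next
    # single capital letter followed by '.' is an initial, not a boundary
    if (grepl("^[A-Z]$", stringr::str_sub(text, pos - 1, pos - 1)) &&
      grepl("^[A-Z.]+$", stringr::str_extract(prefix, "[A-Za-z.]+$") %||% "x")) {
      next
    }
    breaks <- c(breaks, pos)
  }
  starts <- c(1L, integer())
  out <- list()
  cursor <- 1L
  for (b in breaks) {
    # sentence body runs to the punctuation mark; following whitespace belongs
    # to the separator, consumed before the next start
    ws_end <- b
    while (ws_end < nchar(text) &&
      grepl("^\\s$", stringr::str_sub(text, ws_end + 1, ws_end + 1))) {
      ws_end <- ws_end + 1L
    }
    out[[length(out) + 1L]] <- c(cursor, b)
    cursor <- ws_end + 1L
  }
  if (cursor <= nchar(text)) {
    out[[length(out) + 1L]] <- c(cursor, nchar(text))
  }
  if (length(out) == 0) return(empty)
  m <- do.call(rbind, out)
  tibble(
    sentence = stringr::str_sub(text, m[, 1], m[, 2]),
    start = as.integer(m[, 1]),
    end = as.integer(m[, 2])
  )
}

# Stable content id: source db + native id when present, else a hash of the
# normalized title + year (stable across reruns).
make_record_id <- function(source_db, native_id, title, year) {
  purrr::pmap_chr(
    list(source_db, native_id, title, year),
    function(db, nid, ti, yr) {
      if (!is.na(nid) && nzchar(nid)) {
        paste0(db, "_", nid)
      } else {
        paste0(db, "_h", substr(rlang::hash(paste0(normalize_title_key(ti), "|", yr)), 1, 12))
      }
    }
  )
}

# Normalized title key used for dedup matching: case-folded, punctuation and
# whitespace collapsed.
normalize_title_key <- function(title) {
  x <- stringr::str_to_lower(title %||% "")
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  stringr::str_squish(x)
}

normalize_doi <- function(doi) {
  x <- stringr::str_to_lower(stringr::str_trim(doi %||% NA_character_))
  x <- stringr::str_remove(x, "^https?://(dx\\.)?doi\\.org/")
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

# Regex for a lexicon surface variant: case-insensitive, word-bounded,
# hyphen/space tolerant (a hyphen in the variant matches hyphen or space).
variant_regex <- function(variant, boundary_left = TRUE) {
  esc <- stringr::str_replace_all(variant, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
  esc <- stringr::str_replace_all(esc, "[- ]+", "[- ]")
  left <- if (boundary_left) "(?<![A-Za-z0-9])" else ""
  paste0(left, esc, "(?![A-Za-z0-9])")
}

# Canonical key for mapping matched text back to its lexicon variant
# (case-folded, hyphen/space runs collapsed to a single hyphen).
variant_key <- function(x) {
  stringr::str_replace_all(stringr::str_to_lower(x), "[- ]+", "-")
}

# One compiled scanner per lexicon: a single alternation regex with variants
# ordered longest-first, so longer variants win overlaps ("south korea" is
# never also counted as "korea") and only one pass over the text is needed.
compile_lexicon <- function(lexicon) {
  lex <- lexicon[order(-nchar(lexicon$variant)), , drop = FALSE]
  list(
    pattern = stringr::regex(
      paste(purrr::map_chr(unique(lex$variant), variant_regex), collapse = "|"),
      ignore_case = TRUE
    ),
    lookup = setNames(lex$canonical, variant_key(lex$variant)),
    variants = setNames(lex$variant, variant_key(lex$variant))
  )
}

# cache compiled scanners keyed by lexicon content
.lexicon_cache <- new.env(parent = emptyenv())

# Locate all occurrences of lexicon variants in a text. `lexicon` is a tibble
# with columns canonical, variant.
locate_lexicon <- function(text, lexicon) {
  empty <- tibble(
    canonical = character(), variant = character(),
    start = integer(), end = integer()
  )
  if (is.na(text) || !nzchar(text) || nrow(lexicon) == 0) return(empty)
  key <- rlang::hash(lexicon[c("canonical", "variant")])
  scanner <- .lexicon_cache[[key]]
  if (is.null(scanner)) {
    scanner <- compile_lexicon(lexicon)
    .lexicon_cache[[key]] <- scanner
  }
  loc <- stringr::str_locate_all(text, scanner$pattern)[[1]]
  if (nrow(loc) == 0) return(empty)
  matched <- variant_key(stringr::str_sub(text, loc[, 1], loc[, 2]))
  tibble(
    canonical = unname(scanner$lookup[matched]),
    variant = unname(scanner$variants[matched]),
    start = as.integer(loc[, 1]),
    end = as.integer(loc[, 2])
  )
}
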