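test_that("normalize_text replaces typographic dashes and nbsp and is idempotent", {
  expect_equal(normalize_text("tumor–on–chip"), "tumor-on-chip")
  expect_equal(normalize_text("lung organoid"), "lung organoid")
  x <- "a—b – c d"
  y <- normalize_text(x)
  expect_equal(nchar(y), nchar(x))
  # character-by-character oracle: exactly 3 characters change
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  expect_equal(sum(cx != cy), 3L)
  expect_equal(cy[cx != cy], c("-", "-", " "))
  # idempotence on arbitrary text
  samples <- c(x, "plain", "", "em—dash only", "  ", "mixed - – —")
  for (s in samples) expect_equal(normalize_text(normalize_text(s)), normalize_text(s))
  expect_identical(normalize_text(NA_character_), NA_character_)
})

test_that("RIS fixture parses to a hand-checked corpus", {
  path <- write_ris_fixture()
  corp <- parse_metadata_file(path, "ris")
  expect_equal(nrow(corp), 3L)
  expect_equal(corp$title[1], "Colorectal cancer organoids for drug testing")
  expect_equal(corp$keywords[[1]], c("organoid", "colorectal cancer"))
  expect_equal(corp$year, c(2021L, 2022L, 2020L))
  expect_equal(corp$doi[1], "10.1000/fix.1")
  expect_equal(corp$doc_type, c("article", "review", "excluded_type"))
  expect_equal(corp$source_db, rep("embase", 3))
  # en dashes in the abstract are normalized at ingestion
  expect_equal(corp$abstract[2], "A review of tumor-on-chip systems.")
  expect_equal(corp$affiliation_text[1], "Institute A, Oslo, Norway")
  expect_false(anyDuplicated(corp$record_id) > 0)
})

test_that("empty metadata files give empty corpora", {
  for (ext in c(".ris", ".nbib", ".bib")) {
    p <- tempfile(fileext = ext)
    writeLines(character(), p)
    corp <- parse_metadata_file(p)
    expect_equal(nrow(corp), 0L)
  }
})

test_that("nbib parsing handles dashes, continuations and PT priority", {
  path <- write_nbib_fixture()
  corp <- parse_metadata_file(path, "nbib")
  expect_equal(nrow(corp), 2L)
  # en dashes converted to hyphen-minus
  expect_equal(corp$abstract[1], "Liver tumor-organoid co-cultures were grown.")
  expect_equal(corp$doi[1], "10.1000/fix.3")
  # continuation line folded into the abstract
  expect_match(corp$abstract[2], "cultured across multiple passages")
  # Review PT wins over Journal Article
  expect_equal(corp$doc_type, c("article", "review"))
  expect_equal(corp$record_id[1], "pubmed_2001")
})

test_that("BibTeX parsing maps fields and normalizes dois", {
  path <- write_bib_fixture()
  corp <- parse_metadata_file(path, "bib")
  expect_equal(nrow(corp), 2L)
  expect_match(corp$title[1], "Brain tumor organoids")
  expect_equal(corp$doi[1], "10.1000/fix.4") # lower-cased
  expect_equal(corp$keywords[[1]], c("brain organoid", "glioblastoma"))
  expect_equal(corp$year[1], 2020L)
})

test_that("records without a year are rejected with a warning, not silently", {
  p <- tempfile(fileext = ".ris")
  writeLines(c(
    "TY  - JOUR", "TI  - Has a year", "PY  - 2020", "ER  - ",
    "TY  - JOUR", "TI  - No year here", "ER  - "
  ), p)
  expect_warning(corp <- parse_metadata_file(p, "ris"), "without a publication year")
  expect_equal(nrow(corp), 1L)
  expect_equal(corp$title, "Has a year")
})

test_that("document-type filter removes excluded types, keeps order, is idempotent", {
  corp <- make_corpus(
    make_record("a", doc_type = "article"),
    make_record("b", doc_type = "review"),
    make_record("c", doc_type = "excluded_type")
  )
  out <- filter_document_types(corp)
  expect_equal(out$record_id, c("a", "b"))
  only_articles <- make_corpus(make_record("x"), make_record("y"))
  expect_identical(filter_document_types(only_articles), only_articles)
  # 10 records, 4 excluded: 6 survivors in order
  types <- c("article", "excluded_type", "review", "excluded_type", "preprint",
    "article", "excluded_type", "review", "excluded_type", "article")
  big <- dplyr::bind_rows(purrr::map2(
    paste0("r", 1:10), types, ~ make_record(.x, doc_type = .y)
  ))
  surv <- filter_document_types(big)
  expect_equal(nrow(surv), 6L)
  expect_equal(surv$record_id, paste0("r", c(1, 3, 5, 6, 8, 10)))
  expect_identical(filter_document_types(surv), surv)
})

test_that("parse -> serialize -> parse round-trips record content in every dialect", {
  g <- generate_corpus(synthetic_corpus_spec(n_records = 15, seed = 42, duplicate_rate = 0))
  for (dialect in c("ris", "nbib", "bib")) {
    p <- tempfile(fileext = paste0(".", dialect))
    write_metadata_file(g$corpus, p, dialect)
    src <- g$corpus$source_db[1]
    back <- suppressWarnings(parse_metadata_file(p, if (dialect == "bib") "bib" else dialect,
      source_db = "synthetic"))
    expect_equal(nrow(back), nrow(g$corpus))
    expect_equal(back$title, g$corpus$title)
    expect_equal(back$abstract, g$corpus$abstract)
    expect_equal(back$year, g$corpus$year)
    expect_equal(back$doi, g$corpus$doi)
    expect_equal(back$doc_type, g$corpus$doc_type)
    expect_equal(back$affiliation_text, g$corpus$affiliation_text)
    expect_true(all(purrr::map2_lgl(back$keywords, g$corpus$keywords, identical)))
  }
})

test_that("corpus JSONL round-trips including empty corpora", {
  g <- generate_corpus(synthetic_corpus_spec(n_records = 8, seed = 5, duplicate_rate = 0))
  p <- tempfile(fileext = ".jsonl")
  write_corpus(g$corpus, p)
  back <- read_corpus(p)
  expect_equal(back$record_id, g$corpus$record_id)
  expect_equal(back$abstract, g$corpus$abstract)
  expect_equal(back$year, g$corpus$year)
  p2 <- tempfile(fileext = ".jsonl")
  write_corpus(g$corpus[0, ], p2)
  expect_equal(nrow(read_corpus(p2)), 0L)
})
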