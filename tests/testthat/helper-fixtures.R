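# Fixture builders shared across the suite. Everything is generated in code;
# no binary or stored fixtures.

make_record <- function(record_id = "synthetic_r1", abstract = "",
                        title = "", keywords = character(),
                        affiliation_text = "", year = 2021L,
                        doc_type = "article", doi = NA_character_,
                        source_db = "synthetic", native_id = NA_character_) {
  tibble::tibble(
    record_id = record_id, source_db = source_db, native_id = native_id,
    doi = doi, title = title, abstract = abstract,
    keywords = list(keywords), affiliation_text = affiliation_text,
    year = as.integer(year), doc_type = doc_type
  )
}

make_corpus <- function(...) dplyr::bind_rows(...)

# a three-entry RIS fixture (one per doc type), written to a temp file
write_ris_fixture <- function(path = tempfile(fileext = ".ris")) {
  writeLines(c(
    "TY  - JOUR",
    "M3  - Article",
    "AN  - 1001",
    "TI  - Colorectal cancer organoids for drug testing",
    "AB  - We established colorectal cancer organoids.",
    "KW  - organoid",
    "KW  - colorectal cancer",
    "AD  - Institute A, Oslo, Norway",
    "PY  - 2021",
    "DO  - 10.1000/fix.1",
    "ER  - ",
    "TY  - JOUR",
    "M3  - Review",
    "AN  - 1002",
    "TI  - Advances in tumor-on-chip platforms",
    "AB  - A review of tumor–on–chip systems.",
    "KW  - tumor-on-chip",
    "AD  - Unit B, Leiden, Netherlands",
    "PY  - 2022",
    "DO  - 10.1000/fix.2",
    "ER  - ",
    "TY  - JOUR",
    "M3  - Editorial",
    "AN  - 1003",
    "TI  - Comment on chip culture",
    "PY  - 2020",
    "ER  - "
  ), path, useBytes = TRUE)
  path
}

write_nbib_fixture <- function(path = tempfile(fileext = ".nbib")) {
  writeLines(c(
    "PMID- 2001",
    "TI  - Liver organoids in carcinoma research",
    "AB  - Liver tumor–organoid co–cultures were grown.",
    "OT  - liver organoid",
    "AD  - Dept C, Enschede, Netherlands",
    "DP  - 2021 Mar",
    "PT  - Journal Article",
    "LID - 10.1000/fix.3 [doi]",
    "",
    "PMID- 2002",
    "TI  - Pancreatic tumoroids",
    "AB  - Patient-derived pancreatic tumoroids were cultured",
    "      across multiple passages.",
    "DP  - 2022",
    "PT  - Journal Article",
    "PT  - Review"
  ), path, useBytes = TRUE)
  path
}

write_bib_fixture <- function(path = tempfile(fileext = ".bib")) {
  writeLines(c(
    "@article{wos3001,",
    "  title = {Brain tumor organoids {and} their uses},",
    "  abstract = {Glioblastoma organoids recapitulate tumor features.},",
    "  keywords = {brain organoid; glioblastoma},",
    "  affiliation = {Lab D, Uppsala, Sweden},",
    "  year = {2020},",
    "  doi = {10.1000/FIX.4},",
    "  document_type = {Article}",
    "}",
    "",
    "@article{wos3002,",
    "  title = {A duplicate record},",
    "  year = {2019},",
    "  doi = {10.1000/fix.1},",
    "  document_type = {Article}",
    "}"
  ), path, useBytes = TRUE)
  path
}

shared_lexicons <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- oncolit::load_lexicons()
    val
  }
})

shared_taxonomy <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- oncolit::load_taxonomy()
    val
  }
})
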