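lex <- shared_lexicons()
tax <- shared_taxonomy()

test_that("sentence splitting respects abbreviations and reconstructs the input", {
  s1 <- split_sentences("We grew organoids. They were treated.")
  expect_equal(nrow(s1), 2L)
  expect_equal(s1$sentence[1], "We grew organoids.")
  s2 <- split_sentences("Models (e.g. liver organoids) were used.")
  expect_equal(nrow(s2), 1L)
  expect_equal(nrow(split_sentences("")), 0L)
  # concatenation (with separators) reconstructs the input
  texts <- c(
    "One. Two! Three? Four.",
    "Dr. Smith et al. reported results. A second claim followed.",
    "No terminal punctuation here",
    "Spaced.   Sentences.  End."
  )
  for (txt in texts) {
    sp <- split_sentences(txt)
    rebuilt <- paste(purrr::map2_chr(
      sp$start, c(sp$start[-1] - 1, nchar(txt)),
      ~ substr(txt, .x, .y)
    ), collapse = "")
    expect_equal(rebuilt, txt)
  }
})

test_that("model-term detection covers the search vocabulary", {
  r1 <- make_record(abstract = "Patient tumoroids were cultured in matrigel.")
  m1 <- find_model_terms(r1, lex)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$canonical, "tumoroid")
  expect_equal(m1$class, "organoid")
  expect_true(m1$oncological)

  r2 <- make_record(abstract = "A study of fibroblast migration assays.")
  expect_equal(nrow(find_model_terms(r2, lex)), 0L)

  r3 <- make_record(abstract = "heart-on-a-chip and liver-on-chip devices")
  m3 <- find_model_terms(r3, lex)
  expect_equal(nrow(m3), 2L)
  expect_true(all(m3$class == "onchip"))

  # hyphen/space tolerance for on-chip variants
  r4 <- make_record(abstract = "A lung on a chip was perfused.")
  expect_equal(find_model_terms(r4, lex)$class, "onchip")

  # blastoid only counts alongside its required co-occurring term
  r5 <- make_record(abstract = "Blastoids were imaged.")
  expect_equal(nrow(find_model_terms(r5, lex)), 0L)
  r6 <- make_record(abstract = "Blastoids model embryonic development.")
  expect_equal(find_model_terms(r6, lex)$canonical, "blastoid")
})

test_that("organ attachment follows the staged prefix / sentence rules", {
  # organotypic process immediately preceding the on-chip suffix
  a1 <- classify_record(make_record(abstract = "An angiogenesis-on-a-chip platform was built."), lex, tax)
  expect_equal(a1$platform, "ooc")
  expect_equal(a1$organ_aliases[[1]], "angiogenesis")
  expect_equal(a1$detection_method, "prefix")

  # organ only reachable in the same sentence
  a2 <- classify_record(make_record(abstract = "Organoids were derived from liver tumors."), lex, tax)
  expect_equal(a2$organ_aliases[[1]], "liver")
  expect_equal(a2$detection_method, "same_sentence")

  # organ in a different sentence attaches nothing
  a3 <- classify_record(make_record(abstract = "We used organoids. Separately, kidney function was measured."), lex, tax)
  expect_equal(a3$platform, "organoid")
  expect_equal(length(a3$organ_aliases[[1]]), 0L)
  expect_equal(a3$detection_method, "none")

  # organ more than four tokens before the model term is out of the window
  a4 <- classify_record(make_record(abstract = "Liver samples were not the source of our organoids. No other tissue appeared."), lex, tax)
  expect_equal(a4$detection_method, "same_sentence") # sentence rule still fires
  a5 <- classify_record(make_record(abstract = "Liver was processed in one arm of the assay while in parallel plain organoids grew."), lex, tax)
  # distance > 4 tokens but same sentence: attaches via stage 2 only
  expect_equal(a5$detection_method, "same_sentence")
})

test_that("tumor status requires an oncological term in the matched context", {
  t1 <- classify_record(make_record(abstract = "We grew colorectal cancer organoids."), lex, tax)
  expect_true(t1$tumor)
  expect_equal(t1$organ_aliases[[1]], "large_intestine")
  expect_setequal(t1$corpora[[1]], c("organoid", "tumor_organoid"))

  t2 <- classify_record(make_record(abstract = "Intestinal organoids were maintained for weeks."), lex, tax)
  expect_false(t2$tumor)
  expect_equal(t2$corpora[[1]], "organoid")

  # intrinsically oncological model term, no organ anywhere
  t3 <- classify_record(make_record(abstract = "Patient-derived tumoroids were characterized."), lex, tax)
  expect_true(t3$tumor)
  expect_equal(length(t3$organ_aliases[[1]]), 0L)

  # oncological term far from the match and outside the sentence: not a tumor model
  t4 <- classify_record(make_record(
    abstract = "Intestinal organoids were cultured. A separate cohort addressed cancer epidemiology."
  ), lex, tax)
  expect_false(t4$tumor)
})

test_that("routing assigns corpora lineages including dual membership", {
  expect_setequal(route_corpora("organoid", TRUE), c("organoid", "tumor_organoid"))
  expect_equal(route_corpora("organoid", FALSE), "organoid")
  expect_setequal(route_corpora("both", TRUE), c("organoid", "tumor_organoid", "ooc", "toc"))
  expect_equal(route_corpora("none", FALSE), character())

  dual <- classify_record(make_record(
    abstract = "We compared liver cancer organoids with a liver-on-a-chip carcinoma model."
  ), lex, tax)
  expect_equal(dual$platform, "both")
  expect_setequal(dual$corpora[[1]], c("organoid", "tumor_organoid", "ooc", "toc"))

  mps <- classify_record(make_record(
    abstract = "A microphysiological system was used to examine pancreatic tumor growth."
  ), lex, tax)
  expect_setequal(mps$corpora[[1]], c("ooc", "toc"))
})

test_that("manual overrides patch exactly the named records", {
  g <- generate_corpus(synthetic_corpus_spec(n_records = 30, seed = 9, duplicate_rate = 0))
  base <- classify_corpus(g$corpus, lex, tax)
  expect_identical(apply_overrides(base, NULL), base)
  expect_identical(apply_overrides(base, base[0, c("record_id")]), base)

  ov <- tibble::tibble(
    record_id = base$record_id[c(2, 5)],
    organs = c("pituitary", "islet")
  )
  patched <- apply_overrides(base, ov)
  expect_equal(patched$organ_aliases[[2]], "pituitary")
  expect_equal(patched$organ_aliases[[5]], "islet")
  expect_equal(sum(patched$overridden), 2L)
  differs <- purrr::map_lgl(seq_len(nrow(base)), function(i) {
    !identical(base[i, ], patched[i, ])
  })
  expect_equal(which(differs), c(2L, 5L))

  expect_error(
    apply_overrides(base, tibble::tibble(record_id = "nope", organs = "liver")),
    "unknown record id"
  )
})

test_that("prefix rule strictly precedes the sentence rule", {
  base <- make_record(abstract = "We established liver cancer organoids from tissue.")
  plus <- make_record(abstract = paste(
    "We established liver cancer organoids from tissue.",
    "Kidney cancer controls were described elsewhere."
  ))
  a <- classify_record(base, lex, tax)
  b <- classify_record(plus, lex, tax)
  expect_equal(a$detection_method, "prefix")
  expect_equal(b$detection_method, "prefix")
  # adding a sentence-level organ never changes the organs of a prefix match
  expect_equal(sort(a$organ_aliases[[1]]), sort(b$organ_aliases[[1]]))
})

test_that("the rule engine matches the brute-force evaluator record-for-record", {
  tricky <- make_corpus(
    make_record("t1", abstract = "Colorectal cancer organoids and a brain-on-chip model were compared."),
    make_record("t2", abstract = "Organoids grew. Malignant liver tissue was assayed separately."),
    make_record("t3", title = "Pancreatic tumoroid biobanks",
      abstract = "We audited biobanks."),
    make_record("t4", keywords = c("breast cancer organoid"), abstract = "No model terms here."),
    make_record("t5", abstract = "These data may apply to tumor organoids in future."),
    make_record("t6", abstract = "A gastruloid protocol without oncology content."),
    make_record("t7", abstract = "heart on a chip models of carcinoma invasion"),
    make_record("t8", abstract = "Blastoids model embryonic tumors.") # never a tumor model
  )
  g <- generate_corpus(synthetic_corpus_spec(n_records = 40, seed = 21, duplicate_rate = 0))
  corpus <- dplyr::bind_rows(tricky, g$corpus)
  asg <- classify_corpus(corpus, lex, tax)
  for (i in seq_len(nrow(corpus))) {
    o <- oracle_classify(corpus[i, ], lex, tax)
    expect_equal(asg$platform[i], o$platform, info = corpus$record_id[i])
    expect_equal(asg$tumor[i], o$tumor, info = corpus$record_id[i])
    expect_equal(asg$detection_method[i], o$method, info = corpus$record_id[i])
    expect_setequal(asg$organ_aliases[[i]], o$organs)
    expect_setequal(asg$corpora[[i]], o$corpora)
  }
})

test_that("corpus lineages are consistent subsets of platforms", {
  g <- generate_corpus(synthetic_corpus_spec(n_records = 60, seed = 13, duplicate_rate = 0))
  asg <- classify_corpus(g$corpus, lex, tax)
  for (i in seq_len(nrow(asg))) {
    corp <- asg$corpora[[i]]
    if ("tumor_organoid" %in% corp) expect_true("organoid" %in% corp)
    if ("toc" %in% corp) expect_true("ooc" %in% corp)
    if (asg$platform[i] == "organoid") expect_false(any(c("ooc", "toc") %in% corp))
    if (asg$platform[i] == "ooc") expect_false(any(c("organoid", "tumor_organoid") %in% corp))
    if (asg$detection_method[i] == "none") expect_equal(length(asg$organ_aliases[[i]]), 0L)
  }
})
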