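test_that("period counting splits research articles at the 2019/2020 boundary", {
  recs <- make_corpus(
    make_record("a", year = 2018), make_record("b", year = 2019),
    make_record("c", year = 2020), make_record("d", year = 2021)
  )
  expect_equal(unname(count_by_period(recs)), c(2L, 2L))
  expect_equal(unname(count_by_period(recs[0, ])), c(0L, 0L))
  # reviews are not research articles
  with_review <- dplyr::bind_rows(recs, make_record("e", year = 2021, doc_type = "review"))
  expect_equal(unname(count_by_period(with_review)), c(2L, 2L))
  # records before the collection window are ignored
  with_old <- dplyr::bind_rows(recs, make_record("f", year = 2009))
  expect_equal(unname(count_by_period(with_old)), c(2L, 2L))
})

test_that("trend categories follow the strict 40% thresholds", {
  expect_equal(trend_category(100, 159)$category, "high") # 59% above
  expect_equal(trend_category(100, 131)$category, "moderate") # 31% above
  expect_equal(trend_category(10, 10, 1)$category, "moderate")
  expect_equal(trend_category(10, 10, 1)$adjusted_ratio, 1)
  expect_equal(trend_category(10, 5, 1)$category, "low")
  expect_equal(trend_category(10, 5, 1)$adjusted_ratio, 0.5)
  # boundary semantics at +/- 1e-9 of the thresholds (strict inequalities:
  # exactly 1.4 or 0.6 is moderate)
  expect_equal(trend_category(1e9, 1400000000)$category, "moderate")
  expect_equal(trend_category(1e9, 1400000001)$category, "high")
  expect_equal(trend_category(1e9, 600000000)$category, "moderate")
  expect_equal(trend_category(1e9, 599999999)$category, "low")
  # degenerate cells
  expect_equal(trend_category(0, 5)$category, "new")
  expect_equal(trend_category(0, 0)$category, "empty")
  expect_error(trend_category(1, 2, 0), "reference_ratio")
  expect_error(trend_category(1, 2, -1), "reference_ratio")
})

test_that("categories are invariant under uniform scaling of counts", {
  cases <- list(c(10, 25), c(8, 8), c(20, 7), c(5, 9))
  for (cs in cases) {
    base <- trend_category(cs[1], cs[2], 1.1)$category
    for (k in c(2L, 5L, 10L)) {
      expect_equal(trend_category(k * cs[1], k * cs[2], 1.1)$category, base)
    }
  }
})

make_trend_records <- function(group, topic_ids, n_early, n_recent, offset) {
  ids <- paste0(group, "_", paste(topic_ids, collapse = ""), "_", offset, "_",
    seq_len(n_early + n_recent))
  years <- c(rep(2015L, n_early), rep(2021L, n_recent))
  recs <- dplyr::bind_rows(purrr::map2(ids, years, ~ make_record(.x, year = .y)))
  list(
    records = recs,
    groups = tibble::tibble(record_id = ids, group = group),
    topics = if (length(topic_ids) > 0) {
      tidyr::crossing(record_id = ids, topic = topic_ids)
    } else {
      tibble::tibble(record_id = character(), topic = character())
    }
  )
}

test_that("the trend matrix adjusts cells by their column's group ratio", {
  # group A doubles overall (10 -> 20); its topic X cell quadruples (5 -> 20)
  a_x <- make_trend_records("A", "X", 5, 20, 1)
  a_rest <- make_trend_records("A", character(), 5, 0, 2)
  # group B flat (10 -> 10), topic X cell flat too
  b_x <- make_trend_records("B", "X", 10, 10, 3)
  records <- dplyr::bind_rows(a_x$records, a_rest$records, b_x$records)
  groups <- dplyr::bind_rows(a_x$groups, a_rest$groups, b_x$groups)
  topics <- dplyr::bind_rows(a_x$topics, b_x$topics)
  m <- trend_matrix(records, groups, topics)

  top_a <- m[m$group == "A" & is.na(m$topic), ]
  expect_equal(top_a$raw_ratio, 2) # unadjusted top row
  expect_equal(top_a$category, "high")
  cell_ax <- m[m$group == "A" & !is.na(m$topic) & m$topic == "X", ]
  expect_equal(cell_ax$adjusted_ratio, 2) # 4 / 2
  expect_equal(cell_ax$category, "high")
  cell_bx <- m[m$group == "B" & !is.na(m$topic) & m$topic == "X", ]
  expect_equal(cell_bx$adjusted_ratio, 1) # column whose cell ratio equals group ratio
  expect_equal(cell_bx$category, "moderate")
  expect_equal(cell_ax$n_total, 25L)

  # brute-force recount of every cell from the record table
  for (i in seq_len(nrow(m))) {
    g <- m$group[i]
    ids <- groups$record_id[groups$group == g]
    if (!is.na(m$topic[i])) {
      ids <- intersect(ids, topics$record_id[topics$topic == m$topic[i]])
    }
    sel <- records[records$record_id %in% ids & records$doc_type == "article", ]
    expect_equal(m$n_early[i], sum(sel$year < 2020))
    expect_equal(m$n_recent[i], sum(sel$year >= 2020))
  }
})

test_that("an unmentioned topic yields empty cells", {
  a <- make_trend_records("A", character(), 5, 5, 1)
  topics <- tibble::tibble(record_id = character(), topic = character())
  ghost <- tibble::tibble(record_id = a$records$record_id[1], topic = "ghost")[0, ]
  m <- trend_matrix(a$records, a$groups, dplyr::bind_rows(topics, ghost))
  expect_true(all(is.na(m$topic) | m$category == "empty"))
})

test_that("per-category trends adjust against the whole-corpus reference", {
  g <- generate_corpus(synthetic_corpus_spec(n_records = 50, seed = 31, duplicate_rate = 0))
  asg <- classify_corpus(g$corpus, shared_lexicons(), shared_taxonomy())
  res <- resolve_organs(asg, shared_taxonomy())
  tr <- category_trends(g$corpus, res, shared_taxonomy())
  expect_true(all(tr$n_total == tr$n_early + tr$n_recent))
  expect_true(all(tr$category %in% c("high", "moderate", "low", "new", "empty")))
  # recount one category by brute force
  nd <- tr$node[which.max(tr$n_total)]
  ids <- res$record_id[res$node == nd]
  sel <- g$corpus[g$corpus$record_id %in% ids & g$corpus$doc_type == "article" &
    g$corpus$year >= 2011, ]
  expect_equal(tr$n_early[tr$node == nd], sum(sel$year < 2020))
  expect_equal(tr$n_recent[tr$node == nd], sum(sel$year >= 2020))
})
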