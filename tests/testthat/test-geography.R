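geo <- oncolit::load_geo_config()

# an affiliation block in the style of a four-group European collaboration:
# one Norwegian and three Dutch addresses
example_affiliations <- paste(
  "Hybrid Technology Hub, Institute of Basic Medical Sciences, University of Oslo, Oslo, Norway;",
  "Department of Anatomy & Embryology, Leiden University Medical Center, Leiden, The Netherlands;",
  "Center for Stem Cell Medicine, Leiden University Medical Center, Leiden, The Netherlands;",
  "Department of Applied Stem Cell Technologies, University of Twente, Enschede, The Netherlands"
)

test_that("country mentions are counted with variants and first offsets", {
  counts <- count_country_mentions(example_affiliations, geo)
  expect_equal(nrow(counts), 2L)
  expect_equal(counts$n[counts$country == "Norway"], 1L)
  expect_equal(counts$n[counts$country == "Netherlands"], 3L)
  expect_lt(counts$first_offset[counts$country == "Norway"],
    counts$first_offset[counts$country == "Netherlands"])

  expect_equal(nrow(count_country_mentions("", geo)), 0L)

  c2 <- count_country_mentions("Lab 1, Germany; Lab 2, France; Lab 3, Germany", geo)
  expect_equal(c2$n[c2$country == "Germany"], 2L)
  expect_equal(c2$n[c2$country == "France"], 1L)
  expect_lt(c2$first_offset[c2$country == "Germany"], c2$first_offset[c2$country == "France"])

  # overlap masking: "South Korea" is one mention of South Korea, not Korea
  c3 <- count_country_mentions("Institute X, Seoul, South Korea", geo)
  expect_equal(c3$country, "South Korea")
  expect_equal(c3$n, 1L)
})

test_that("the main country maximizes counts with earliest-mention tie-break", {
  expect_equal(main_country(count_country_mentions(example_affiliations, geo)), "Netherlands")
  tie <- count_country_mentions("Lab A, Germany; Lab B, France", geo)
  expect_equal(main_country(tie), "Germany")
  expect_true(is.na(main_country(count_country_mentions("no countries here", geo))))
})

test_that("fractional contributions divide counts by the total", {
  fr <- fractional_contributions(count_country_mentions(example_affiliations, geo))
  expect_equal(fr$fraction[fr$country == "Norway"], 0.25)
  expect_equal(fr$fraction[fr$country == "Netherlands"], 0.75)

  single <- fractional_contributions(count_country_mentions("Lab, Japan", geo))
  expect_equal(single$fraction, 1.0)

  equal3 <- fractional_contributions(
    count_country_mentions("A, Spain; B, Italy; C, Poland", geo)
  )
  expect_equal(equal3$fraction, rep(1 / 3, 3))
  expect_lt(abs(sum(equal3$fraction) - 1), 1e-12)
})

test_that("aggregation computes ERA rollups, per-capita activity and conserves mass", {
  corp <- make_corpus(
    make_record("r1", affiliation_text = "Lab, Oslo, Norway"),
    make_record("r2", affiliation_text = "Lab, Bergen, Norway"),
    make_record("r3", affiliation_text = "Lab A, USA; Lab B, USA; Lab C, Japan"),
    make_record("r4", affiliation_text = "")
  )
  at <- attribute_countries(corp, geo)
  agg <- aggregate_geography(at, geo)
  era_row <- agg[agg$country == "ERA", ]
  expect_equal(era_row$n_main, 2L) # both wholly-Norwegian records
  expect_equal(era_row$frac_sum, 2)
  # conservation: fractional mass equals records with any mention
  expect_equal(sum(agg$frac_sum[agg$country != "ERA"]), 3)
  # per-capita scale: fractional sum per million inhabitants
  nor <- agg[agg$country == "Norway", ]
  expect_equal(nor$frac_per_million, 2 / (geo$countries$population[
    geo$countries$country == "Norway"] / 1e6))
  # main-country counts never exceed records mentioning the country
  expect_lte(agg$n_main[agg$country == "Japan"], 1L)

  expect_equal(nrow(aggregate_geography(at[0, ], geo)), 0L)
})

test_that("aggregates are invariant under record order", {
  g <- generate_corpus(synthetic_corpus_spec(n_records = 25, seed = 8, duplicate_rate = 0))
  at <- attribute_countries(g$corpus, geo)
  a1 <- aggregate_geography(at, geo)
  at_perm <- at[rev(seq_len(nrow(at))), ]
  a2 <- aggregate_geography(at_perm, geo)
  expect_equal(
    dplyr::arrange(a1, country),
    dplyr::arrange(a2, country)
  )
})

test_that("a country without a population entry is a configuration error", {
  fake <- tibble::tibble(
    record_id = "r", country = "Atlantis", n = 1L, first_offset = 1L,
    fraction = 1, is_main = TRUE
  )
  expect_error(aggregate_geography(fake, geo), "missing from config")
})

test_that("ERA membership covers EU-27 plus UK and 18 associated countries", {
  expect_equal(sum(geo$countries$era_member), 46L)
  expect_true(all(c("UK", "Switzerland", "Norway", "Israel", "Turkey") %in%
    geo$countries$country[geo$countries$era_member]))
  expect_false(any(c("USA", "China", "Japan") %in%
    geo$countries$country[geo$countries$era_member]))
})
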