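Package: oncolit
Title: Text-Mining Pipeline for Tumor Organoid and Tumor-on-Chip Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quality-controlled, rule-based text-mining pipeline for mapping
    the research landscape of three-dimensional tumor models (tumor organoids,
    tumor-on-chip and microphysiological systems) from publication metadata.
    Parses RIS, PubMed nbib and BibTeX exports into normalized records,
    deduplicates within and across database pulls, detects culture-platform
    mentions and attaches organs of origin with proximity rules (a four-token
    prefix window with a same-sentence fallback), assigns tumor status from an
    oncological lexicon, maps organs onto a hierarchical taxonomy, annotates
    research topics from nested synonym lists, attributes records to countries
    with fractional counting and European Research Area rollups, scores
    early-versus-recent publication trends against corpus references, fits
    log-linear publication-growth regressions with share projections, and
    classifies clinical-trial registry records. A synthetic-corpus generator
    with ground-truth labels makes every stage testable without licensed
    database extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
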