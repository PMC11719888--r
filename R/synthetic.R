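#' @title Synthetic corpora with ground truth
#' @description
#' Generates publication corpora, trial tables and yearly series with known
#' ground-truth labels, so that every pipeline stage is testable without
#' licensed database extracts. Abstracts are built from sentence templates
#' that place organ aliases at controlled token distances from model terms
#' (inside or outside the four-token prefix window, in the same or a
#' different sentence), plant oncological terms per case class, instantiate
#' affiliations from country templates with known counts, and emit
#' cross-database duplicates with publication-year drift.
#'
#' Truth labels are defined by the rules (what the staged rule engine should
#' say); a separate semantic-truth column records what a human reader would
#' say, so the rules' intrinsic error on hard negatives (e.g. "may in future
#' be applied to tumor organoids") is measurable.
#' @name synthetic_data
NULL

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Largest-remainder apportionment of n into proportional integer counts
#'
#' Exact, deterministic allocation: floors first, then distributes the
#' remaining units by descending fractional remainder (ties by position).
#'
#' @param n Total count.
#' @param props Non-negative proportions (normalized internally).
#' @return Integer vector summing to `n`, same names as `props`.
#' @export
largest_remainder <- function(n, props) {
  p <- props / sum(props)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(setNames(base, names(props)))
}

# organ aliases planted in templates, with their leaf taxonomy nodes
synthetic_organ_pool <- function() tibble(
  alias = c(
    "liver", "lung", "pancreatic", "colon", "prostate", "breast",
    "gastric", "brain", "ovarian", "bladder", "kidney", "thyroid"
  ),
  node = c(
    "liver", "lung", "pancreas", "large_intestine", "prostate", "breast",
    "stomach", "brain", "ovary", "bladder", "kidney", "thyroid"
  ),
  # taxonomy resolution of the planted alias (brain is non-leaf: its sole
  # detection resolves to the unspecified child)
  resolved = c(
    "liver", "lung", "pancreas", "large_intestine", "prostate", "breast",
    "stomach", "brain_un", "ovary", "bladder", "kidney", "thyroid"
  )
)

# topics safe to plant: no oncological / organ / model vocabulary in variants
synthetic_topic_pool <- function() tibble(
  topic = c(
    "personalized_medicine", "immunotherapy", "chemotherapy", "radiotherapy",
    "drug_development", "drug_delivery", "high_throughput", "apoptosis",
    "autophagy", "hypoxia", "biobank", "gene_editing", "bioprinting",
    "omics", "macrophage", "dendritic_cell", "extracellular_vesicle",
    "raman_spectroscopy", "murine"
  ),
  phrase = c(
    "precision medicine", "immunotherapy", "chemotherapy", "radiotherapy",
    "drug development", "drug delivery", "high-throughput workflows",
    "apoptosis", "autophagy", "hypoxia", "biobank construction",
    "gene editing", "3D bioprinting", "transcriptomics", "macrophages",
    "dendritic cells", "exosomes", "Raman spectroscopy", "murine husbandry"
  )
)

default_country_pool <- c(
  "USA", "China", "Germany", "Netherlands", "UK", "Japan", "South Korea",
  "France", "Italy", "Switzerland", "Norway", "Sweden", "Canada",
  "Australia", "Spain"
)

#' Specification of a synthetic corpus
#'
#' The generation parameters: record count, RNG seed, year range and yearly
#' growth, the mix of planted case classes, the truth-label noise rate, the
#' country profile and the cross-database duplicate rate (duplicates carry a
#' one-year publication-year drift, emulating the electronic-to-print shift
#' between two acquisition rounds).
#'
#' Case classes: `prefix_tumor_organoid` (organ + oncological term inside the
#' four-token prefix window), `sentence_tumor_organoid` (organ only reachable
#' by the sentence rule), `nontumor_organoid`, `toc` (organ-on-a-chip prefix
#' with tumor context), `mps` (microphysiological system, sentence rule),
#' `distractor` (model term merely mentioned; the rules are expected to call
#' it a tumor-organoid mention, the semantic truth says none) and `no_model`.
#'
#' @param n_records Number of base records.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @param year_range Two-element integer range of publication years.
#' @param growth Either `"uniform"` or a two-element `c(a, b)` on the ln
#'   scale; yearly volumes follow `exp(b * year)` (the intercept cancels in
#'   the within-range allocation).
#' @param case_mix Named proportions over the case classes (must sum to 1).
#' @param noise_rate Fraction of records whose *stored truth label* is
#'   deliberately perturbed (in `[0, 0.5]`); emulates classifier
#'   misclassification for validation-protocol experiments.
#' @param country_pool Countries drawn for affiliation templates.
#' @param duplicate_rate Fraction of records duplicated into a second source
#'   database with year drift +1.
#' @param doc_type_mix Named proportions over document types.
#' @return A `synthetic_corpus_spec` list.
#' @export
synthetic_corpus_spec <- function(n_records = 500L, seed = 1L,
                                  year_range = c(2011L, 2023L),
                                  growth = c(a = 0, b = 0.40315),
                                  case_mix = c(
                                    prefix_tumor_organoid = 0.30,
                                    sentence_tumor_organoid = 0.15,
                                    nontumor_organoid = 0.20,
                                    toc = 0.10,
                                    mps = 0.05,
                                    distractor = 0.10,
                                    no_model = 0.10
                                  ),
                                  noise_rate = 0,
                                  country_pool = default_country_pool,
                                  duplicate_rate = 0.10,
                                  doc_type_mix = c(
                                    article = 0.80, review = 0.15,
                                    excluded_type = 0.05
                                  )) {
  if (abs(sum(case_mix) - 1) > 1e-8) abort("case_mix must sum to 1")
  if (noise_rate < 0 || noise_rate > 0.5) abort("noise_rate must be in [0, 0.5]")
  structure(
    list(
      n_records = as.integer(n_records), seed = as.integer(seed),
      year_range = as.integer(year_range), growth = growth,
      case_mix = case_mix, noise_rate = noise_rate,
      country_pool = country_pool, duplicate_rate = duplicate_rate,
      doc_type_mix = doc_type_mix
    ),
    class = "synthetic_corpus_spec"
  )
}

# case-class templates; {organ} is replaced by a planted alias
synthetic_abstract <- function(case_class, organ_alias) {
  switch(case_class,
    prefix_tumor_organoid = sprintf(
      "We established %s cancer organoids from surgical specimens.", organ_alias
    ),
    sentence_tumor_organoid = sprintf(
      "Organoids were generated to examine %s carcinoma behaviour.", organ_alias
    ),
    nontumor_organoid = sprintf(
      "%s organoids were differentiated from adult stem cells in this work.",
      stringr::str_to_sentence(organ_alias)
    ),
    toc = sprintf(
      "We fabricated a %s-on-a-chip device to recapitulate carcinoma physiology.",
      organ_alias
    ),
    mps = sprintf(
      "A microphysiological system was used to examine %s tumor progression.",
      organ_alias
    ),
    distractor = "These findings may in future be applied to tumor organoids in the clinic.",
    no_model = sprintf(
      "We profiled gene expression in %s tumor biopsies from patients.", organ_alias
    )
  )
}

# rule-truth labels per case class
synthetic_truth_for <- function(case_class, node) {
  switch(case_class,
    prefix_tumor_organoid = list(
      platform = "organoid", tumor = TRUE, organs = node, method = "prefix",
      corpora = c("organoid", "tumor_organoid"),
      sem_platform = "organoid", sem_tumor = TRUE
    ),
    sentence_tumor_organoid = list(
      platform = "organoid", tumor = TRUE, organs = node, method = "same_sentence",
      corpora = c("organoid", "tumor_organoid"),
      sem_platform = "organoid", sem_tumor = TRUE
    ),
    nontumor_organoid = list(
      platform = "organoid", tumor = FALSE, organs = node, method = "prefix",
      corpora = "organoid", sem_platform = "organoid", sem_tumor = FALSE
    ),
    toc = list(
      platform = "ooc", tumor = TRUE, organs = node, method = "prefix",
      corpora = c("ooc", "toc"), sem_platform = "ooc", sem_tumor = TRUE
    ),
    mps = list(
      platform = "ooc", tumor = TRUE, organs = node, method = "same_sentence",
      corpora = c("ooc", "toc"), sem_platform = "ooc", sem_tumor = TRUE
    ),
    distractor = list(
      platform = "organoid", tumor = TRUE, organs = character(), method = "none",
      corpora = c("organoid", "tumor_organoid"),
      sem_platform = "none", sem_tumor = FALSE
    ),
    no_model = list(
      platform = "none", tumor = FALSE, organs = character(), method = "none",
      corpora = character(), sem_platform = "none", sem_tumor = FALSE
    )
  )
}

#' Generate a synthetic corpus with ground truth
#'
#' @param spec A [synthetic_corpus_spec()].
#' @param out_dir Optional directory; when given, the corpus is also written
#'   as `embase.ris`, `pubmed.nbib` and `scopus.bib` (records split across
#'   simulated source databases, duplicates included) plus `truth.csv`.
#' @return A list: `corpus` (base records), `duplicates` (cross-database
#'   duplicate copies with year drift +1), `truth` (one row per base record:
#'   rule-truth platform/tumor/organs/method/corpora/topics/main country,
#'   resolved node, semantic truth, and `label` = platform|tumor|node used by
#'   agreement experiments), and `files` (paths, when written). Deterministic
#'   given the spec (same spec + seed = byte-identical outputs).
#' @export
generate_corpus <- function(spec = synthetic_corpus_spec(), out_dir = NULL) {
  n <- spec$n_records
  if (n == 0) {
    return(list(corpus = empty_corpus(), duplicates = empty_corpus(),
      truth = synthetic_truth_skeleton(), files = character()))
  }
  years_all <- seq(spec$year_range[1], spec$year_range[2])
  with_seed(spec$seed, {
    # case classes and doc types by largest remainder, then shuffled
    counts <- largest_remainder(n, spec$case_mix)
    case_class <- sample(rep(names(spec$case_mix), counts))
    dt_counts <- largest_remainder(n, spec$doc_type_mix)
    doc_type <- sample(rep(names(spec$doc_type_mix), dt_counts))
    # yearly volumes follow the growth law
    wt <- if (identical(spec$growth, "uniform")) {
      rep(1, length(years_all))
    } else {
      exp(spec$growth[["b"]] * (years_all - min(years_all)))
    }
    year <- sample(years_all, n, replace = TRUE, prob = wt / sum(wt))
    organ_pool <- synthetic_organ_pool()
    topic_pool <- synthetic_topic_pool()
    organ_idx <- sample(nrow(organ_pool), n, replace = TRUE)
    src_cycle <- c("embase", "pubmed", "scopus")
    source_db <- src_cycle[(seq_len(n) - 1) %% 3 + 1]

    rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- case_class[i]
      organ <- organ_pool[organ_idx[i], ]
      tr <- synthetic_truth_for(cls, organ$node)
      # topic sentences
      n_topics <- sample(0:3, 1)
      tset <- if (n_topics > 0) {
        topic_pool[sample(nrow(topic_pool), n_topics), ]
      } else {
        topic_pool[0, ]
      }
      topic_sent <- if (nrow(tset) > 0) {
        paste0(" The work additionally considered ", paste(tset$phrase, collapse = " and "), ".")
      } else {
        ""
      }
      abstract <- paste0(
        synthetic_abstract(cls, organ$alias),
        topic_sent,
        " Samples were processed with standardized workflows."
      )
      # affiliations with known country counts; first country is the main one
      k <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
      countries <- sample(spec$country_pool, k)
      c1 <- sample(1:3, 1)
      m <- c(c1, if (k > 1) sample(1:c1, k - 1, replace = TRUE))
      aff <- paste(unlist(purrr::map2(countries, m, function(cn, times) {
        sprintf("Institute %s, Unit %d, %s", LETTERS[sample(26, times, replace = TRUE)],
          seq_len(times), cn)
      })), collapse = "; ")
      rows[[i]] <- tibble(
        record_id = paste0(source_db[i], "_syn", i),
        source_db = source_db[i],
        native_id = paste0("syn", i),
        doi = sprintf("10.5555/synth.%05d", i),
        title = sprintf("Quantitative study %d of three-dimensional culture approaches", i),
        abstract = abstract,
        keywords = list(c("3D culture", "preclinical analysis")),
        affiliation_text = aff,
        year = year[i],
        doc_type = doc_type[i]
      )
      truth_rows[[i]] <- tibble(
        record_id = rows[[i]]$record_id,
        case_class = cls,
        true_platform = tr$platform,
        true_tumor = tr$tumor,
        true_organs = list(tr$organs),
        true_method = tr$method,
        true_corpora = list(tr$corpora),
        true_node = if (length(tr$organs) > 0) organ$resolved else "unidentified",
        true_topics = list(sort(tset$topic)),
        true_main_country = countries[1],
        semantic_platform = tr$sem_platform,
        semantic_tumor = tr$sem_tumor
      )
    }
    corpus <- bind_rows(rows)
    truth <- bind_rows(truth_rows) %>%
      mutate(label = paste(.data$true_platform, .data$true_tumor, .data$true_node, sep = "|"))
    if (spec$noise_rate > 0) truth <- perturb_truth(truth, spec$noise_rate)

    # cross-database duplicates with year drift +1
    n_dup <- as.integer(floor(spec$duplicate_rate * n))
    duplicates <- if (n_dup > 0) {
      idx <- sort(sample(n, n_dup))
      dup <- corpus[idx, ]
      alt <- src_cycle[(match(dup$source_db, src_cycle)) %% 3 + 1]
      dup %>% mutate(
        source_db = alt,
        record_id = paste0(alt, "_syn", idx, "d"),
        native_id = paste0("syn", idx, "d"),
        year = .data$year + 1L
      )
    } else {
      empty_corpus()
    }

    files <- character()
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      full <- bind_rows(corpus, duplicates)
      files <- c(
        ris = file.path(out_dir, "embase.ris"),
        nbib = file.path(out_dir, "pubmed.nbib"),
        bib = file.path(out_dir, "scopus.bib")
      )
      write_metadata_file(full %>% filter(.data$source_db == "embase"), files[["ris"]], "ris")
      write_metadata_file(full %>% filter(.data$source_db == "pubmed"), files[["nbib"]], "nbib")
      write_metadata_file(full %>% filter(.data$source_db == "scopus"), files[["bib"]], "bib")
      truth_path <- file.path(out_dir, "truth.csv")
      flat <- truth %>% mutate(
        true_organs = purrr::map_chr(.data$true_organs, paste, collapse = ";"),
        true_corpora = purrr::map_chr(.data$true_corpora, paste, collapse = ";"),
        true_topics = purrr::map_chr(.data$true_topics, paste, collapse = ";")
      )
      utils::write.csv(flat, truth_path, row.names = FALSE)
      files <- c(files, truth = truth_path)
    }
    list(corpus = corpus, duplicates = duplicates, truth = truth, files = files)
  })
}

synthetic_truth_skeleton <- function() {
  tibble(
    record_id = character(), case_class = character(),
    true_platform = character(), true_tumor = logical(),
    true_organs = list(), true_method = character(), true_corpora = list(),
    true_node = character(), true_topics = list(),
    true_main_country = character(), semantic_platform = character(),
    semantic_tumor = logical(), label = character()
  )
}

#' Perturb stored truth labels (planted classification noise)
#'
#' Flips the `label` of a fraction of records to a different value drawn
#' from the observed label set, marking them `perturbed`. Emulates the
#' misclassification rate of a rule-based classifier so that
#' validation-protocol experiments have a known expected agreement.
#'
#' @param truth Truth tibble with a `label` column.
#' @param noise_rate Fraction perturbed.
#' @param seed Optional seed (when called outside [generate_corpus()]).
#' @return The truth tibble with perturbed labels and a `perturbed` flag.
#' @export
perturb_truth <- function(truth, noise_rate, seed = NULL) {
  run <- function() {
    n <- nrow(truth)
    n_flip <- as.integer(round(noise_rate * n))
    truth$perturbed <- FALSE
    if (n_flip == 0) return(truth)
    idx <- sample(n, n_flip)
    pool <- unique(truth$label)
    for (i in idx) {
      others <- setdiff(pool, truth$label[i])
      if (length(others) == 0) others <- paste0(truth$label[i], "*")
      truth$label[i] <- sample(others, 1)
    }
    truth$perturbed[idx] <- TRUE
    truth
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a yearly publication series from a growth law
#'
#' Counts are `round(exp(a + b * year))` (noise `"none"`) or Poisson draws
#' with that mean (`"poisson"`); deterministic given the seed. Every mean in
#' range must be at least 1.
#'
#' @param a,b Log-linear coefficients.
#' @param years Integer years.
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed for Poisson noise.
#' @return A tibble `year`, `count`.
#' @export
generate_yearly_series <- function(a, b, years, noise = c("none", "poisson"),
                                   seed = 1L) {
  noise <- match.arg(noise)
  mu <- exp(a + b * years)
  if (any(mu < 1)) {
    abort("expected count below 1 within the year range; shrink the range")
  }
  counts <- if (noise == "none") {
    as.integer(round(mu))
  } else {
    with_seed(seed, as.integer(rpois(length(mu), mu)))
  }
  tibble(year = as.integer(years), count = counts)
}

#' Agreement between predictions and truth on random record subsets
#'
#' The validation-protocol analogue: samples `n_subsets` disjoint subsets of
#' `subset_size` records, computes the per-subset agreement percentage
#' between predicted and true labels, and returns their mean and standard
#' deviation (as percentages).
#'
#' @param truth Tibble `record_id`, `label`.
#' @param predictions Tibble `record_id`, `label` covering all truth records.
#' @param n_subsets Number of disjoint subsets (default 3).
#' @param subset_size Records per subset (default 24).
#' @param seed RNG seed for the subset draw.
#' @return A one-row tibble `mean_pct`, `sd_pct`, with the per-subset rates
#'   in the `rates` attribute.
#' @export
match_rate_experiment <- function(truth, predictions, n_subsets = 3L,
                                  subset_size = 24L, seed = 1L) {
  joined <- inner_join(truth, predictions, by = "record_id",
    suffix = c("_true", "_pred"))
  need <- n_subsets * subset_size
  if (nrow(joined) < need) {
    abort(sprintf(
      "corpus too small for %d disjoint subsets of %d (have %d records)",
      n_subsets, subset_size, nrow(joined)
    ))
  }
  with_seed(seed, {
    idx <- sample(nrow(joined), need)
    rates <- purrr::map_dbl(seq_len(n_subsets), function(s) {
      sub <- joined[idx[((s - 1) * subset_size + 1):(s * subset_size)], ]
      100 * mean(sub$label_true == sub$label_pred)
    })
    out <- tibble(mean_pct = mean(rates), sd_pct = sd(rates))
    attr(out, "rates") <- rates
    out
  })
}
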