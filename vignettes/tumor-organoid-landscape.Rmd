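---
title: "Mining the tumor-organoid and tumor-on-chip literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the tumor-organoid and tumor-on-chip literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolit)
library(dplyr)
```

## The problem and the method

Tumor organoids and tumor-on-chip (ToC) platforms are the two main families
of three-dimensional in vitro tumor models. Mapping their research landscape
means classifying thousands of publication records — titles, keywords,
abstracts, affiliations, years, document types — by culture platform, organ
of origin, tumor status, research topic and country, then scoring how each
slice of the landscape grows. `oncolit` implements this as a deterministic,
rule-based pipeline. No statistical or neural NLP is involved: the method's
value is that it is transparent, reproducible and auditable, and its known
cost is a quantifiable misclassification rate that the package's validation
tooling makes measurable.

### Ingestion and normalization

Records arrive in the three export dialects literature databases actually
produce (RIS, PubMed nbib, BibTeX). Two normalizations happen at ingestion,
for *all* sources, because downstream matching is token-based: em and en
dashes become plain hyphens and non-breaking spaces become plain spaces
(`normalize_text()`, a total, idempotent function). Field mappings per
dialect are explicit constants (RIS `TI`/`AB`/`KW`/`AD`/`PY`/`DO`/`AN`; nbib
`TI`/`AB`/`OT`/`AD`/`DP`/`PT`/`LID`; the BibTeX
`title`/`abstract`/`keywords`/`affiliation`/`year`/`doi` fields); unmapped
tags are ignored. Records without a recoverable publication year are
rejected with a warning — never silently. Record identifiers combine the
source database with its native id when present, else a content hash of the
normalized title and year, so identifiers are stable across reruns. Records
with an empty abstract are kept, because titles and keywords are still
searched.

Document types are normalized to `article` / `review` / `preprint` /
`excluded_type`; the excluded class covers comments, editorials, retracted
articles and retraction notices. "Research article" throughout means the
non-review class as labelled by the source database, so opinion pieces
typed as articles are included — a known property of the data source, not
of this implementation.

### Deduplication and acquisition merging

Deduplication is exact-key: same non-empty DOI first, else same normalized
title (case-folded, punctuation and whitespace collapsed). Two records with
*different* non-empty DOIs are never merged on title. The survivor of a
duplicate group is chosen by a documented source priority (pubmed > embase >
scopus > wos > biorxiv), then original order. An edit-distance tolerance on
titles exists behind `dedup_policy(title_max_dist = )` but is off by
default: determinism and auditability outrank recall here, and the fuzzy
matchers common in reference-management tooling have unstated parameters
that make results hard to reproduce.

Merging an update acquisition handles publication-year drift: when a record
appears in both pulls (the overlap window exists precisely to catch the
electronic-to-print year shift), the retained record keeps every field from
the older pull *except the year*, which is taken from the newer pull. The
set identity `|merged| = |old| + |new| − |matches|` is asserted against a
brute-force pairwise matcher in the tests.

### The staged proximity rules

The classifier answers three questions per record: which platform (organoid
vs on-chip/MPS), which organ, and is it a tumor model.

*Platform terms* are a configurable lexicon: the organoid family (organoid,
enteroid, colonoid, assembloid, gastruloid, iblastoid, tumoroid with
British/American spellings and plurals), the on-chip suffix variants
(`on-chip`, `on-chips`, `on-a-chip`, hyphen or space), and the
microphysiological-system spellings. Blastoid terms are represented but
gated on a co-occurring "embryonic" and can never produce tumor models.

*Organ attachment* is staged:

1. **Prefix rule.** An organ alias whose final token lies within the four
   tokens immediately preceding an organoid-class term attaches to it. For
   on-chip terms the organ alias — or an organotypic process such as
   angiogenesis — must immediately precede the suffix, hyphen- or
   space-joined (`liver-on-a-chip`, `angiogenesis on a chip`).
2. **Sentence rule**, evaluated only when the prefix rule attached nothing:
   organ aliases in any sentence that contains a platform term attach.

A *token* is a maximal run of letters, digits and hyphens after
case-folding; "within four words" means the alias's final token sits at
distance 1–4 before the term's first token. The tokenizer had to be pinned
down somewhere, and this definition keeps hyphenated compounds
(`non-small-cell`) intact. Sentence boundaries are sentence-final
punctuation followed by whitespace, with a shipped abbreviation exception
list (e.g., i.e., et al., Fig., vs., ca.); the splitter reconstructs its
input exactly, which the tests assert.

*Tumor status* requires an oncological term in the matched context. For
prefix matches we read "context" as a symmetric four-token window around
the organ–model span; the window is symmetric because tumor vocabulary
follows the platform term about as often as it precedes it
(`liver-on-a-chip model of carcinoma invasion`), and a purely backward
window would miss those while adding no precision on synthetic benchmarks
constructed from either reading. For sentence-stage matches the context is
the matched sentence. Tumoroid/tumouroid terms are intrinsically
oncological. Finally, an attached organ is retained as a *tumor* organ only
if an oncological term co-occurs with that organ alias somewhere in the
title, keywords or abstract (window or sentence) — this is the step that
separates the tumor organ from a co-mentioned healthy-tissue organ in
records that use both model types. We apply this retention check to the
whole searchable text rather than only to matched sentences, the more
permissive of the two defensible readings, because abstracts routinely name
the researched tumor type in a different sentence from the model
description.

Records route to corpora by platform and tumor flag: organoid →
`organoid` (+`tumor_organoid` when tumor), on-chip/MPS → `ooc` (+`toc`),
with dual-platform records carrying both lineages. A manual-override table
(`apply_overrides()`) models the curation pass for infrequently studied
organs; overridden records are flagged.

### Taxonomy resolution

Detected aliases map to nodes of a three-level organ forest (systems,
organs, substructures; the gastrointestinal and neural branches use the
third level). Resolution rules, in order: neuroendocrine yields to any
concrete organ (so "neuroendocrine prostate cancer" is prostate); ancestors
of detected nodes are dropped in favour of the deepest detection; nodes
spanning two or more top-level systems resolve to `multiple_organs`;
several branches within one system resolve to their nearest common
ancestor's UN (unspecified) child; a sole non-leaf detection resolves to its
own UN child; no detection at all is `unidentified`. `multiple_organs` only
triggers *across* systems because within-system ambiguity is better
represented by the parent's UN bucket than by an "everything" category.
Resolution is deterministic and order-independent (asserted by permutation
tests), and every record gets exactly one category, so categories partition
each corpus for counting.

Regrouping schemes reconcile taxonomy categories with external groupings:
`default` is the identity, `system` rolls up to organ systems, and the
shipped `incidence` scheme matches cancer-statistics conventions (biliary →
liver, islet → pancreas). Scheme lookups walk from the node toward the
root; a gap along the whole path is a configuration error, never a silent
`NA`.

### Topics, geography, trends, growth

Topic annotation is substring-at-word-boundary matching of nested synonym
lists (no stemming — the lists themselves carry the writing variants), with
set semantics per record. Monotonicity (more text never removes a topic)
is a tested property.

Country attribution counts gazetteer names in the affiliation block,
longest variant first so "South Korea" never also counts as "Korea". The
main country is the most-mentioned one, ties broken by earliest mention
(typically the first author's country). Fractional counts divide each
country's mentions by all country mentions and therefore sum to one per
record — a conservation law the acceptance tests assert. The European
Research Area rollup sums the EU-27 (including the former member UK) plus
18 associated countries; membership, name variants and the population
snapshot (2023 reference, per-million scaling) are configuration, because
they are facts about the world, not about the method.

Trends compare research-article counts in 2011–2019 against 2020 onward.
The raw ratio `n_recent / n_early` is divided by a reference ratio — the
whole corpus for per-organ trends, the tumor group's own ratio for cells of
the group × topic matrix — and labelled `high` above 1.4, `low` below 0.6,
`moderate` otherwise. Both thresholds are strict: exactly 1.4 is moderate,
and the tests pin this at ±1e−9 of the boundary. The nine-versus-three-plus
year asymmetry of the two periods is deliberately *not* corrected, because
every adjusted ratio divides two like-constructed ratios and the asymmetry
cancels; only the top "trend" row of the matrix, which is reported raw (a
documented choice — the alternative reading adjusts it against the whole
corpus), carries the asymmetry visibly. Cells with `n_early = 0` and
recent activity are labelled `new` rather than given an undefined ratio.
Given the classifier's roughly 10% misclassification rate, differences
smaller than the 40% band should not be over-interpreted; the categorical
output encodes exactly that caution.

Publication growth is ordinary least squares of `ln(count)` on the raw
calendar year, `ln(y) = a + b·x`. Raw years produce intercepts near −800;
this is numerically harmless at these scales and keeps coefficients
directly comparable with the reference regressions, but
`fit_loglinear(center = TRUE)` fits on centered years and back-transforms
for the cautious. Years with zero counts abort the fit with instructions to
restrict the range — silently dropping them would bias the slope. Reported
statistics are `r²`, `adj r² = 1 − (1−r²)(n−1)/(n−2)`,
`F = (n−2)·r²/(1−r²)` and the upper-tail F(1, n−2) p-value;
`implied_adjusted_r2()` inverts the F statistic for consistency checks
against printed values. The share of corpus A within corpus B is the ratio
of the two fitted exponentials, `exp((a_A−a_B) + (b_A−b_B)·x)`; with the
reference coefficient pairs it crosses 1% in 2025 and 5% in 2030, and
`threshold_year()` is tested for agreement with a brute-force year scan.

### Clinical trials

Registry exports (legacy CSV layout with Conditions / Study Designs /
Status columns; a column map accommodates others) are filtered of withdrawn
trials, flagged by platform term set, and classified by primary purpose
(the token sequence after `Primary Purpose:` in the pipe-delimited design
text) and tumor group. The tumor grouping reuses the same alias scan and
hierarchy rules as publications, and a test feeds identical phrases through
both paths to hold that consistency.

## The synthetic-corpus generator

The generator is first-class, tested code, not a fixture. It emulates the
structural features of multi-database metadata the pipeline must handle:

- abstracts built from sentence templates that place organ aliases at
  controlled token distances from model terms (inside the four-token prefix
  window, reachable only by the sentence rule, or absent), with oncological
  terms planted per case class;
- the seven case classes cover prefix tumor organoids, sentence-rule tumor
  organoids, non-tumor organoids, organ-on-a-chip with tumor context, MPS
  mentions, hard-negative distractors and no-model records, with default
  mix 30/15/20/10/5/10/10 % — tumor organoids deliberately dominate, since
  that is the corpus under study;
- yearly volumes following `exp(b·x)` with the reference slope 0.40315 by
  default, over 2011–2023;
- affiliation strings instantiated from country templates with known
  mention counts (the first-listed country is constructed to be the main
  one);
- cross-database duplicates at rate 0.10 with a +1-year publication-year
  drift, emulating the two-acquisition overlap;
- a document-type mix of 80% articles, 15% reviews, 5% excluded types.

Truth labels are defined **by the rules** — what the staged engine should
say — with a separate semantic-truth column for what a reader would say.
The distractor class ("may in future be applied to tumor organoids") is the
point of that split: the rules are *expected* to classify it as a
tumor-organoid mention, and the gap between rule truth and semantic truth
is the rules' intrinsic error, measurable but not a bug. Case-mix counts
use largest-remainder apportionment, so non-integral proportions allocate
exactly and deterministically; generation is byte-identical given the seed.

What the generator does **not** emulate: real abstract language (templates
are rigid), negation ("we did not use organoids"), cross-sentence
anaphora, misspelled organ names, per-journal metadata quirks, or
multi-language records. Passing the exact-recovery test therefore shows the
engine implements its stated rules correctly on text the rules can parse —
it does not bound the rules' error on real abstracts. That error is instead
what the validation-protocol analogue quantifies: with 10% planted label
noise, three disjoint n = 24 subsets give a mean agreement whose
distribution (a hypergeometric draw of 72 from 500 with 50 perturbed) lies
in the 80–98% band in well over 95% of seeds.

## Problem sizes and numerical choices

The test suite exercises corpora of 15–120 records per module and one
500-record corpus for the end-to-end and validation checks; the slope
recovery experiment uses 500 Poisson-noised series of 12 years. These sizes
make every property exhaustive (the brute-force evaluator re-derives every
record) while a full run stays in the minutes range on one core.
Tolerances: coefficient recovery on noiseless series at 1e−6 on the slope
(rounding-free construction) and 1e−2 after integer rounding; implied
adjusted r² against printed statistics at 1.5e−4 (the F statistics are
printed to one decimal); fractional-count conservation at 1e−12; trend
boundaries at ±1e−9. Ties everywhere break deterministically (first by
priority order, then by original position), and every export is a pure
function of inputs and configuration — reruns are byte-identical, which is
itself a tested invariant.

## Known limitations

- The method reads titles, keywords and abstracts only; models described
  exclusively in full text are invisible.
- Terminology dependence: work that avoids the on-chip/MPS vocabulary is
  not retrievable, so chip corpora are conservative.
- Rule-based matching has no negation or hedging detection; the distractor
  machinery exists precisely to keep that error measurable.
- The shipped taxonomy, topic lists, gazetteer and constants cover the
  categories used in the main analyses; complete curated inventories from
  any specific study must be supplied as configuration for exact parity.
- Exact-key deduplication will keep near-duplicates whose titles differ by
  more than case and punctuation unless the edit-distance option is
  enabled.
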