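#' Deduplication policy
#'
#' Controls how duplicate records are matched: by normalized DOI first, then
#' by normalized title (case-folded, punctuation and whitespace collapsed,
#' exact match). An optional edit-distance tolerance on normalized titles is
#' available but off by default (determinism first). The overlap window marks
#' the re-acquisition period whose records may legitimately appear in both
#' pulls.
#'
#' @param key_order Ordered match keys; DOI is always tried before title.
#' @param overlap_start First year of the re-acquisition overlap window.
#' @param title_max_dist Maximum edit distance between normalized titles to
#'   count as a match (0 = exact).
#' @return A `dedup_policy` list.
#' @export
dedup_policy <- function(key_order = c("doi", "title"), overlap_start = 2022L,
                         title_max_dist = 0L) {
  if (length(key_order) == 0) abort("key_order must be non-empty")
  if ("doi" %in% key_order && "title" %in% key_order &&
    which(key_order == "title") < which(key_order == "doi")) {
    abort("doi must be tried before title")
  }
  structure(
    list(
      key_order = key_order, overlap_start = as.integer(overlap_start),
      title_max_dist = as.integer(title_max_dist)
    ),
    class = "dedup_policy"
  )
}

# Survivor priority when duplicates span source databases.
source_priority <- c("pubmed", "embase", "scopus", "wos", "biorxiv", "synthetic")

source_rank <- function(source_db) {
  r <- match(source_db, source_priority)
  r[is.na(r)] <- length(source_priority) + 1L
  r
}

# Assign a duplicate-group id per record under the policy keys.
dedup_groups <- function(corpus, policy) {
  n <- nrow(corpus)
  group <- seq_len(n)
  if ("doi" %in% policy$key_order && n > 0) {
    has_doi <- !is.na(corpus$doi)
    group[has_doi] <- match(corpus$doi[has_doi], corpus$doi) # first index per doi
  }
  if ("title" %in% policy$key_order && n > 0) {
    key <- normalize_title_key(corpus$title)
    if (policy$title_max_dist > 0) {
      # greedy approximate clustering on normalized titles
      for (i in seq_len(n)) {
        if (group[i] != i) next
        d <- utils::adist(key[i], key)
        hits <- which(d <= policy$title_max_dist)
        group[hits] <- pmin(group[hits], group[i])
      }
    } else {
      title_first <- match(key, key)
      # two records with distinct non-empty dois are never title-merged
      ok <- is.na(corpus$doi) | is.na(corpus$doi[title_first]) |
        corpus$doi == corpus$doi[title_first]
      group[ok] <- pmin(group[ok], group[title_first[ok]])
    }
  }
  group
}

#' Remove duplicate records within a corpus
#'
#' Records with the same non-empty DOI (else the same normalized title) form
#' a duplicate group; exactly one survives, chosen by source priority
#' (pubmed > embase > scopus > wos > biorxiv), then by original order.
#' Idempotent.
#'
#' @param corpus A corpus tibble.
#' @param policy A [dedup_policy()].
#' @return The deduplicated corpus, survivors in their original order.
#' @export
dedup_corpus <- function(corpus, policy = dedup_policy()) {
  if (nrow(corpus) == 0) return(corpus)
  group <- dedup_groups(corpus, policy)
  ord <- order(group, source_rank(corpus$source_db), seq_len(nrow(corpus)))
  keep_idx <- ord[!duplicated(group[ord])]
  corpus[sort(keep_idx), ]
}

# For each record in `new`, the matching row index in `old` (NA if none),
# doi key first, then normalized title.
match_records <- function(old, new, policy) {
  m <- rep(NA_integer_, nrow(new))
  if ("doi" %in% policy$key_order) {
    has <- !is.na(new$doi)
    m[has] <- match(new$doi[has], old$doi)
  }
  if ("title" %in% policy$key_order) {
    old_key <- normalize_title_key(old$title)
    new_key <- normalize_title_key(new$title)
    for (i in which(is.na(m))) {
      cand <- which(old_key == new_key[i])
      # records with distinct non-empty dois never title-match
      ok <- cand[is.na(new$doi[i]) | is.na(old$doi[cand]) | old$doi[cand] == new$doi[i]]
      if (length(ok) > 0) m[i] <- ok[1]
    }
  }
  m
}

#' Merge an update acquisition into an existing corpus
#'
#' Publication years drift when a record moves from electronic to printed
#' publication between two database pulls. For records present in both
#' corpora the retained record keeps every field from the older pull except
#' the year, which is taken from the newer pull; the new copy is then
#' discarded. Unmatched new records are appended.
#'
#' @param old Corpus from the first acquisition.
#' @param new Corpus from the update acquisition (expected to be dated on or
#'   after `policy$overlap_start`; earlier records are processed with a
#'   warning).
#' @param policy A [dedup_policy()].
#' @return The merged corpus: `nrow = nrow(old) + nrow(new) - matches`.
#' @export
merge_acquisitions <- function(old, new, policy = dedup_policy()) {
  if (nrow(new) == 0) return(old)
  early <- !is.na(new$year) & new$year < policy$overlap_start
  if (any(early)) {
    warn(sprintf(
      "%d update record(s) dated before the overlap window start (%d); processed anyway",
      sum(early), policy$overlap_start
    ))
  }
  if (nrow(old) == 0) return(new)
  m <- match_records(old, new, policy)
  matched <- !is.na(m)
  out <- old
  if (any(matched)) out$year[m[matched]] <- new$year[matched]
  bind_rows(out, new[!matched, ])
}
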