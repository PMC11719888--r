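#' Load the hierarchical organ/substructure taxonomy
#'
#' The taxonomy is a forest of organ systems (level 1), organs (level 2) and
#' substructures (level 3; the gastrointestinal and neural branches carry the
#' extra level). Every node lists surface aliases; every alias must resolve
#' to exactly one node. "UN" (unspecified) children are generated for every
#' non-leaf node at load time and receive publications recognized only at the
#' parent level. Scheme blocks give per-scheme regrouping labels (e.g., the
#' incidence-comparison scheme maps cholangiocarcinoma-bearing biliary models
#' into the liver group).
#'
#' @param path Path to a taxonomy YAML file; `NULL` for the shipped default.
#' @return A `taxonomy` list with tibbles `nodes` (`node_id`, `label`,
#'   `parent`, `level`, `system`, `is_un`), `aliases` (`canonical` = node id,
#'   `variant`) and `schemes` (`node_id`, `scheme`, `group`).
#' @export
load_taxonomy <- function(path = NULL) {
  path <- path %||% system.file("extdata", "taxonomy.yaml", package = "oncolit")
  cfg <- yaml::read_yaml(path)
  nodes <- list(); aliases <- list(); schemes <- list()
  walk_node <- function(node, parent, level, system) {
    id <- node$id
    if (is.null(id)) abort("taxonomy node without an id")
    if (level > 3) abort(sprintf("taxonomy node '%s' deeper than 3 levels", id))
    nodes[[length(nodes) + 1L]] <<- tibble(
      node_id = id, label = node$label %||% id, parent = parent,
      level = level, system = system %||% id, is_un = FALSE
    )
    for (a in node$aliases %||% list()) {
      aliases[[length(aliases) + 1L]] <<- tibble(
        canonical = id, variant = stringr::str_to_lower(a)
      )
    }
    for (s in names(node$schemes %||% list())) {
      schemes[[length(schemes) + 1L]] <<- tibble(
        node_id = id, scheme = s, group = node$schemes[[s]]
      )
    }
    kids <- node$children %||% list()
    for (child in kids) walk_node(child, id, level + 1L, system %||% id)
    if (length(kids) > 0) {
      nodes[[length(nodes) + 1L]] <<- tibble(
        node_id = paste0(id, "_un"), label = "UN", parent = id,
        level = level + 1L, system = system %||% id, is_un = TRUE
      )
    }
  }
  for (sys in cfg$systems) walk_node(sys, NA_character_, 1L, NULL)
  tax <- list(
    nodes = bind_rows(nodes),
    aliases = if (length(aliases) > 0) bind_rows(aliases) else
      tibble(canonical = character(), variant = character()),
    schemes = if (length(schemes) > 0) bind_rows(schemes) else
      tibble(node_id = character(), scheme = character(), group = character())
  )
  class(tax) <- "taxonomy"
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  dup <- tax$aliases %>% count(.data$variant) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    claimed <- tax$aliases %>% filter(.data$variant %in% dup$variant)
    abort(sprintf(
      "taxonomy alias(es) claimed by more than one node: %s",
      paste(unique(paste0(claimed$variant, " (", claimed$canonical, ")")), collapse = ", ")
    ))
  }
  if (anyDuplicated(tax$nodes$node_id)) abort("duplicate taxonomy node id")
  # parent links must form a forest with level(child) = level(parent) + 1
  for (i in seq_len(nrow(tax$nodes))) {
    seen <- character()
    cur <- tax$nodes$node_id[i]
    while (!is.na(cur)) {
      if (cur %in% seen) abort(sprintf("taxonomy cycle through node '%s'", cur))
      seen <- c(seen, cur)
      j <- match(cur, tax$nodes$node_id)
      p <- tax$nodes$parent[j]
      if (!is.na(p)) {
        k <- match(p, tax$nodes$node_id)
        if (is.na(k)) abort(sprintf("node '%s' has unknown parent '%s'", cur, p))
        if (tax$nodes$level[j] != tax$nodes$level[k] + 1L) {
          abort(sprintf("node '%s' level is not parent level + 1", cur))
        }
      }
      cur <- p
    }
  }
  invisible(tax)
}

# Ancestor path from the root down to (excluding) the node.
taxonomy_ancestors <- function(tax, node_id) {
  out <- character()
  cur <- tax$nodes$parent[match(node_id, tax$nodes$node_id)]
  while (!is.na(cur)) {
    out <- c(cur, out)
    cur <- tax$nodes$parent[match(cur, tax$nodes$node_id)]
  }
  out
}

taxonomy_children <- function(tax, node_id) {
  tax$nodes$node_id[!is.na(tax$nodes$parent) & tax$nodes$parent == node_id]
}

#' Resolve detected organ aliases to a single taxonomy category
#'
#' Applies the resolution rules: (a) the neuroendocrine node only stands when
#' it is the sole detected category, otherwise the other organ wins; (b) a
#' record recognized only at an upper-level category maps to that category's
#' "UN" (unspecified) child; (c) nothing resolvable maps to `unidentified`;
#' (d) detections spanning two or more distinct top-level organ systems map
#' to `multiple_organs`, while multiple nodes within one system map to their
#' nearest common ancestor's UN child. Deterministic and order-independent.
#'
#' @param detected Character vector of detected canonical node ids (organ
#'   aliases already canonicalized by the classifier; unknown entries, e.g.
#'   organotypic processes, are ignored).
#' @param taxonomy A [load_taxonomy()] object.
#' @return Character scalar: a node id, `"<node>_un"`, `"unidentified"` or
#'   `"multiple_organs"`.
#' @export
assign_hierarchy <- function(detected, taxonomy = load_taxonomy()) {
  nodes <- sort(unique(detected[detected %in% taxonomy$nodes$node_id]))
  if (length(nodes) == 0) return("unidentified")
  if ("neuroendocrine" %in% nodes && length(nodes) > 1) {
    nodes <- setdiff(nodes, "neuroendocrine")
  }
  # drop nodes that are ancestors of other detected nodes (keep the deepest)
  is_ancestor <- purrr::map_lgl(nodes, function(nd) {
    any(purrr::map_lgl(setdiff(nodes, nd), ~ nd %in% taxonomy_ancestors(taxonomy, .x)))
  })
  nodes <- nodes[!is_ancestor]
  systems <- unique(taxonomy$nodes$system[match(nodes, taxonomy$nodes$node_id)])
  if (length(systems) > 1) return("multiple_organs")
  if (length(nodes) == 1) {
    if (length(taxonomy_children(taxonomy, nodes)) > 0) {
      return(paste0(nodes, "_un"))
    }
    return(nodes)
  }
  # several sibling branches within one system: nearest common ancestor's UN
  paths <- purrr::map(nodes, ~ c(taxonomy_ancestors(taxonomy, .x), .x))
  depth <- min(lengths(paths))
  common <- NA_character_
  for (d in seq_len(depth)) {
    at_d <- unique(purrr::map_chr(paths, d))
    if (length(at_d) == 1) common <- at_d[1] else break
  }
  paste0(common, "_un")
}

#' Resolve organ categories for a whole assignment table
#'
#' @param assignments Assignment tibble from [classify_corpus()].
#' @param taxonomy A [load_taxonomy()] object.
#' @param scheme Scheme name used for `group` (see [regroup_for_scheme()]);
#'   `"default"` keeps top-level system labels.
#' @return A tibble `record_id`, `node` (resolved category), `group`
#'   (scheme label).
#' @export
resolve_organs <- function(assignments, taxonomy = load_taxonomy(),
                           scheme = "default") {
  nodes <- purrr::map_chr(assignments$organ_aliases, assign_hierarchy, taxonomy = taxonomy)
  tibble(
    record_id = assignments$record_id,
    node = nodes,
    group = regroup_for_scheme(nodes, taxonomy, scheme)
  )
}

#' Map resolved categories through a regrouping scheme
#'
#' Two schemes are built in: `"default"` is the identity (a category keeps
#' its own label; in particular top-level categories map to themselves) and
#' `"system"` rolls every node up to its top-level organ system. Named
#' schemes from the config (e.g. `"incidence"`) look the group label up at
#' the node, walking toward the root when absent; a node with no mapping
#' anywhere on its path is a configuration error. `unidentified` and
#' `multiple_organs` map to themselves under every scheme.
#'
#' @param nodes Character vector of resolved node ids (UN children allowed).
#' @param taxonomy A [load_taxonomy()] object.
#' @param scheme Scheme name (e.g. `"incidence"`), `"system"` or `"default"`.
#' @return Character vector of group labels.
#' @export
regroup_for_scheme <- function(nodes, taxonomy = load_taxonomy(), scheme = "default") {
  purrr::map_chr(nodes, function(nd) {
    if (nd %in% c("unidentified", "multiple_organs")) return(nd)
    if (scheme == "default") return(nd)
    base <- if (nd %in% taxonomy$nodes$node_id) nd else stringr::str_remove(nd, "_un$")
    if (!base %in% taxonomy$nodes$node_id) {
      abort(sprintf("unknown taxonomy node '%s'", nd))
    }
    if (scheme == "system") {
      return(taxonomy$nodes$system[match(base, taxonomy$nodes$node_id)])
    }
    if (taxonomy$nodes$is_un[match(base, taxonomy$nodes$node_id)]) {
      base <- taxonomy$nodes$parent[match(base, taxonomy$nodes$node_id)]
    }
    for (cand in c(base, rev(taxonomy_ancestors(taxonomy, base)))) {
      hit <- taxonomy$schemes %>%
        filter(.data$node_id == cand, .data$scheme == !!scheme)
      if (nrow(hit) > 0) return(hit$group[1])
    }
    abort(sprintf("node '%s' has no mapping for scheme '%s'", nd, scheme))
  })
}

#' Serialize a taxonomy back to YAML
#'
#' Writes the nested `systems:` layout that [load_taxonomy()] reads, so that
#' load -> serialize -> load round-trips the structure.
#'
#' @param taxonomy A [load_taxonomy()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
serialize_taxonomy <- function(taxonomy, path) {
  build <- function(id) {
    i <- match(id, taxonomy$nodes$node_id)
    out <- list(id = id, label = taxonomy$nodes$label[i])
    al <- taxonomy$aliases$variant[taxonomy$aliases$canonical == id]
    if (length(al) > 0) out$aliases <- as.list(al)
    sc <- taxonomy$schemes %>% filter(.data$node_id == id)
    if (nrow(sc) > 0) out$schemes <- as.list(setNames(sc$group, sc$scheme))
    kids <- setdiff(taxonomy_children(taxonomy, id),
      taxonomy$nodes$node_id[taxonomy$nodes$is_un])
    if (length(kids) > 0) out$children <- purrr::map(kids, build)
    out
  }
  roots <- taxonomy$nodes$node_id[is.na(taxonomy$nodes$parent)]
  yaml::write_yaml(list(systems = purrr::map(roots, build)), path)
  invisible(path)
}

# Human-readable node path ("gastrointestinal/intestine/large_intestine").
node_path <- function(taxonomy, node_id) {
  purrr::map_chr(node_id, function(nd) {
    if (nd %in% c("unidentified", "multiple_organs")) return(nd)
    paste(c(taxonomy_ancestors(taxonomy, nd), nd), collapse = "/")
  })
}
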