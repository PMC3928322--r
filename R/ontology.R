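# OBO parsing and DAG queries over is_a / part_of relations.

#' Parse an OBO 1.2 ontology file into a DAG
#'
#' Reads `[Term]` stanzas from an OBO flat file and builds a directed acyclic
#' graph over GO terms. Only `is_a:` lines and `relationship: part_of` lines
#' create edges; every other relationship type (`regulates`, `has_part`, ...)
#' is ignored, because annotation propagation and developmental-subtree
#' membership are both defined over is_a and part_of alone. Obsolete terms are
#' retained and flagged but never given edges, so annotations that still
#' reference them fail loudly downstream rather than silently propagating.
#'
#' @param path path to an OBO file.
#' @param resolve_alt_ids if `TRUE` (default), `alt_id:` accessions are
#'   recorded and term lookups through [go_ancestors()] etc. resolve them to
#'   their primary term.
#' @return a `go_ontology` object: a list with a `terms` tibble
#'   (`term_id`, `name`, `namespace`, `is_obsolete`), an `edges` tibble
#'   (`child`, `parent`, `relation`), parent/child adjacency lists, and an
#'   `alt_map` named vector.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process"
#' ), obo)
#' onto <- parse_obo(obo)
#' onto$terms
#' @export
parse_obo <- function(path, resolve_alt_ids = TRUE) {
  .assert_file_exists(path)
  lines <- readLines(path, warn = FALSE)

  stanza_starts <- which(lines == "[Term]")
  terms <- vector("list", length(stanza_starts))
  edge_rows <- vector("list", length(stanza_starts))
  boundaries <- c(grep("^\\[", lines), length(lines) + 1L)

  for (i in seq_along(stanza_starts)) {
    start <- stanza_starts[i]
    end <- min(boundaries[boundaries > start]) - 1L
    body <- lines[(start + 1L):end]
    body <- body[nzchar(body)]

    field <- function(key) {
      hits <- grep(paste0("^", key, ":"), body, value = TRUE)
      trimws(sub(paste0("^", key, ":\\s*"), "", hits))
    }

    id <- field("id")
    if (length(id) != 1L || !is_go_accession(id)) {
      abort(sprintf("malformed [Term] stanza at line %d: missing or invalid id", start))
    }
    name <- field("name")
    namespace <- field("namespace")
    obsolete <- identical(field("is_obsolete"), "true")
    alt_ids <- field("alt_id")

    # strip trailing "! comment" from is_a / relationship targets
    is_a <- sub("\\s*!.*$", "", field("is_a"))
    rel <- sub("\\s*!.*$", "", field("relationship"))
    part_of <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])

    if (obsolete) {
      is_a <- character()
      part_of <- character()
    }
    if (id %in% c(is_a, part_of)) {
      abort(sprintf("term %s lists itself as a parent (line %d)", id, start))
    }

    terms[[i]] <- tibble(
      term_id = id,
      name = if (length(name)) name[1] else "",
      namespace = if (length(namespace)) namespace[1] else NA_character_,
      is_obsolete = obsolete,
      alt_ids = list(alt_ids)
    )
    edge_rows[[i]] <- bind_rows(
      if (length(is_a)) tibble(child = id, parent = is_a, relation = "is_a"),
      if (length(part_of)) tibble(child = id, parent = part_of, relation = "part_of")
    )
  }

  term_tbl <- bind_rows(terms)
  if (anyDuplicated(term_tbl$term_id)) {
    abort("duplicate term ids in OBO file")
  }
  edges <- bind_rows(edge_rows)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(child = character(), parent = character(), relation = character())
  }

  missing_parents <- setdiff(edges$parent, term_tbl$term_id)
  if (length(missing_parents)) {
    abort(sprintf(
      "parent term(s) referenced but not defined: %s",
      paste(missing_parents, collapse = ", ")
    ))
  }

  alt_map <- character()
  if (resolve_alt_ids) {
    alt_tbl <- term_tbl %>%
      select("term_id", "alt_ids") %>%
      tidyr::unnest("alt_ids")
    if (nrow(alt_tbl)) {
      if (anyDuplicated(alt_tbl$alt_ids) || any(alt_tbl$alt_ids %in% term_tbl$term_id)) {
        abort("alt_id does not resolve uniquely to one primary term")
      }
      alt_map <- setNames(alt_tbl$term_id, alt_tbl$alt_ids)
    }
  }

  onto <- structure(
    list(
      terms = term_tbl %>% select(-"alt_ids"),
      edges = edges,
      parents = .adjacency(edges$child, edges$parent, term_tbl$term_id),
      children = .adjacency(edges$parent, edges$child, term_tbl$term_id),
      alt_map = alt_map
    ),
    class = "go_ontology"
  )
  .check_acyclic(onto)
  onto
}

.adjacency <- function(from, to, universe) {
  adj <- split(to, factor(from, levels = universe))
  lapply(adj, unique)
}

# Kahn's algorithm; on failure, walks parent links to exhibit one cycle.
.check_acyclic <- function(onto) {
  ids <- onto$terms$term_id
  indeg <- vapply(onto$children[ids], length, integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (p in onto$parents[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(ids)) {
    start <- ids[indeg > 0L][1L]
    path <- start
    v <- start
    repeat {
      nxt <- intersect(onto$parents[[v]], ids[indeg > 0L])[1L]
      if (nxt %in% path) {
        cycle <- c(path[which(path == nxt):length(path)], nxt)
        abort(sprintf("cyclic is_a/part_of structure: %s", paste(cycle, collapse = " -> ")))
      }
      path <- c(path, nxt)
      v <- nxt
    }
  }
  invisible(onto)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf(
    "<go_ontology> %d terms (%d obsolete), %d edges (%d is_a, %d part_of)\n",
    nrow(x$terms), sum(x$terms$is_obsolete), nrow(x$edges),
    sum(x$edges$relation == "is_a"), sum(x$edges$relation == "part_of")
  ))
  invisible(x)
}

#' Resolve a term id through alt_id mapping
#'
#' @param onto a `go_ontology`.
#' @param term_id GO accession (primary or alternate).
#' @return the primary accession, or an error if the term is unknown.
#' @export
resolve_term <- function(onto, term_id) {
  if (term_id %in% names(onto$alt_map)) {
    term_id <- unname(onto$alt_map[[term_id]])
  }
  if (!term_id %in% onto$terms$term_id) {
    abort(sprintf("unknown term id: %s", term_id))
  }
  term_id
}

.traverse <- function(adj, start) {
  out <- character()
  frontier <- adj[[start]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(adj[new], use.names = FALSE))
  }
  setdiff(unique(out), start)
}

#' Ancestors of a term
#'
#' Transitive closure over is_a and part_of edges in the parent direction,
#' excluding the query term itself — the set of terms an annotation to
#' `term_id` implicitly annotates under the true path rule.
#'
#' @param onto a `go_ontology`.
#' @param term_id GO accession.
#' @return character vector of ancestor accessions (possibly empty).
#' @export
go_ancestors <- function(onto, term_id) {
  .traverse(onto$parents, resolve_term(onto, term_id))
}

#' Descendants of a term
#'
#' Transitive closure in the child direction over is_a and part_of edges.
#' With the developmental-process root this defines the developmental subtree
#' used to gate ortholog transfer; see [dev_subtree()].
#'
#' @inheritParams go_ancestors
#' @return character vector of descendant accessions (possibly empty).
#' @export
go_descendants <- function(onto, term_id) {
  .traverse(onto$children, resolve_term(onto, term_id))
}

#' Developmental subtree membership set
#'
#' The root together with all of its descendants. The default root is
#' GO:0032502 ("developmental process"); it is a parameter because other
#' branches may be used to scope a transfer.
#'
#' @param onto a `go_ontology`.
#' @param dev_root accession of the subtree root.
#' @return character vector: `dev_root` plus its descendants.
#' @export
dev_subtree <- function(onto, dev_root = "GO:0032502") {
  root <- resolve_term(onto, dev_root)
  c(root, go_descendants(onto, root))
}

# Ancestor sets for many terms at once via dynamic programming in topological
# order; equals repeated go_ancestors() but linear in total edge count.
.ancestor_sets <- function(onto) {
  ids <- onto$terms$term_id
  anc <- setNames(vector("list", length(ids)), ids)
  done <- setNames(logical(length(ids)), ids)
  order <- .topo_order(onto)
  for (t in order) {
    ps <- onto$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    done[[t]] <- TRUE
  }
  anc
}

# parents before children is not needed; we need parents' ancestor sets first,
# so emit terms in an order where every parent precedes its children's use:
# process in decreasing depth from roots via Kahn on the parent relation.
.topo_order <- function(onto) {
  ids <- onto$terms$term_id
  # count unresolved parents per term; roots first
  remaining <- vapply(onto$parents[ids], length, integer(1))
  queue <- ids[remaining == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in onto$children[[v]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Per-namespace term and edge counts
#'
#' @param onto a `go_ontology`.
#' @return tibble with one row per namespace: term, obsolete and edge counts.
#' @export
ontology_stats <- function(onto) {
  edge_ns <- onto$edges %>%
    left_join(onto$terms %>% select("term_id", "namespace"),
      by = c(child = "term_id")
    ) %>%
    count(.data$namespace, name = "n_edges")
  onto$terms %>%
    group_by(.data$namespace) %>%
    summarise(
      n_terms = n(),
      n_obsolete = sum(.data$is_obsolete),
      .groups = "drop"
    ) %>%
    left_join(edge_ns, by = "namespace") %>%
    mutate(n_edges = tidyr::replace_na(.data$n_edges, 0L))
}

#' Serialize a `go_ontology` back to OBO
#'
#' Deterministic writer (terms in their stored order) so that
#' `parse_obo(write_obo(x))` preserves term count, edge count and edge types,
#' and equal graphs serialize byte-identically.
#'
#' @param onto a `go_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  alt_by_primary <- if (length(onto$alt_map)) {
    split(names(onto$alt_map), unname(onto$alt_map))
  } else {
    list()
  }
  for (i in seq_len(nrow(onto$terms))) {
    row <- onto$terms[i, ]
    id <- row$term_id
    stanza <- c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", row$name),
      if (!is.na(row$namespace)) paste0("namespace: ", row$namespace),
      vapply(alt_by_primary[[id]] %||% character(), function(a) paste0("alt_id: ", a), ""),
      if (row$is_obsolete) "is_obsolete: true",
      {
        e <- onto$edges[onto$edges$child == id, ]
        c(
          paste0("is_a: ", e$parent[e$relation == "is_a"], recycle0 = TRUE),
          paste0("relationship: part_of ", e$parent[e$relation == "part_of"],
            recycle0 = TRUE
          )
        )
      },
      ""
    )
    writeLines(stanza, con)
  }
  invisible(path)
}
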