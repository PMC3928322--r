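# Gene-set collections: true-path propagation, GMT I/O, size filtering.

NAMESPACE_ASPECTS <- c(
  biological_process = "P",
  molecular_function = "F",
  cellular_component = "C"
)

.norm_namespace <- function(namespace) {
  if (namespace %in% names(NAMESPACE_ASPECTS)) {
    return(namespace)
  }
  hit <- names(NAMESPACE_ASPECTS)[NAMESPACE_ASPECTS == toupper(namespace)]
  if (!length(hit)) {
    abort(sprintf("unknown namespace/aspect: %s", namespace))
  }
  hit
}

new_geneset_collection <- function(sets, names_map, namespace, metadata = list()) {
  structure(
    list(sets = sets, names = names_map, namespace = namespace, metadata = metadata),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf(
    "<geneset_collection> %d sets (%s), sizes %s\n",
    length(x$sets), x$namespace,
    if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"
  ))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' Tidy a gene-set collection
#'
#' @param x a `geneset_collection`.
#' @param ... unused.
#' @return tibble with one row per set: `term_id`, `name`, `n_genes`, and a
#'   `genes` list-column.
#' @method tidy geneset_collection
#' @export
tidy.geneset_collection <- function(x, ...) {
  tibble(
    term_id = names(x$sets),
    name = unname(x$names[names(x$sets)]),
    n_genes = lengths(x$sets),
    genes = unname(x$sets)
  )
}

#' Build a propagated gene-set collection from an annotation corpus
#'
#' Implements the construction used to turn a merged annotation corpus into
#' GO-term gene sets:
#'
#' 1. NOT-qualified records are excluded;
#' 2. the evidence policy is applied, except that ortholog-derived records
#'    (provenance `ORTHOLOG`) are always admitted;
#' 3. each surviving gene–term pair contributes the gene symbol to the term's
#'    set and, under the true path rule, to every ancestor's set along is_a
#'    and part_of edges;
#' 4. only terms of the requested namespace are emitted, and empty sets are
#'    omitted.
#'
#' Records whose term is absent from the ontology, or is obsolete, are skipped
#' with a reported count. Symbols are uppercased on ingestion so human and
#' ortholog-derived records collide correctly.
#'
#' @param records annotation tibble.
#' @param onto a `go_ontology`.
#' @param namespace GO aspect to emit: `"biological_process"` (default),
#'   `"molecular_function"`, `"cellular_component"`, or the one-letter
#'   aspect codes P/F/C.
#' @param policy evidence policy; default [geneset_policy()].
#' @param quiet suppress the skipped-record message.
#' @return a `geneset_collection`.
#' @export
build_collection <- function(records, onto, namespace = "biological_process",
                             policy = geneset_policy(), quiet = FALSE) {
  namespace <- .norm_namespace(namespace)

  rec <- records[!.has_not(records$qualifiers), , drop = FALSE]
  is_ortho <- vapply(rec$provenances, function(p) "ORTHOLOG" %in% p, logical(1))
  passes <- rec$evidence_code %in% policy$whitelist &
    !rec$evidence_code %in% policy$blacklist
  rec <- rec[is_ortho | passes, , drop = FALSE]

  if (nrow(rec) && length(onto$alt_map)) {
    hit <- match(rec$term_id, names(onto$alt_map))
    rec$term_id[!is.na(hit)] <- unname(onto$alt_map[hit[!is.na(hit)]])
  }
  known <- rec$term_id %in% onto$terms$term_id
  obsolete_ids <- onto$terms$term_id[onto$terms$is_obsolete]
  usable <- known & !rec$term_id %in% obsolete_ids
  n_skipped <- sum(!usable)
  if (n_skipped && !quiet) {
    inform(sprintf(
      "build_collection: skipped %d record(s) (%d unknown term, %d obsolete term)",
      n_skipped, sum(!known), sum(known & !usable)
    ))
  }
  rec <- rec[usable, , drop = FALSE]

  pairs <- tibble(
    symbol = .norm_symbol(rec$symbol),
    term_id = rec$term_id
  ) %>% distinct()

  anc <- .ancestor_sets(onto)
  ns_terms <- onto$terms$term_id[
    !is.na(onto$terms$namespace) & onto$terms$namespace == namespace &
      !onto$terms$is_obsolete
  ]

  sets <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    terms <- c(pairs$term_id[i], anc[[pairs$term_id[i]]])
    for (t in terms) {
      sets[[t]] <- c(sets[[t]], pairs$symbol[i])
    }
  }
  out_ids <- sort(intersect(ls(sets), ns_terms))
  out <- lapply(setNames(out_ids, out_ids), function(t) sort(unique(sets[[t]])))
  out <- out[lengths(out) > 0L]

  names_map <- setNames(onto$terms$name, onto$terms$term_id)
  new_geneset_collection(
    out, names_map[names(out)], namespace,
    metadata = list(
      policy = policy, n_records = nrow(records),
      n_skipped = n_skipped, built = "build_collection"
    )
  )
}

#' Write / read GMT gene-set files
#'
#' One tab-delimited line per set: set name, description, then the member
#' genes. The set name is the GO term name (falling back to the accession) and
#' the description column carries the GO accession, so collections survive a
#' round trip keyed by accession. Genes are written in lexicographic order for
#' reproducible diffs.
#'
#' @param collection a `geneset_collection`.
#' @param path file path.
#' @return `write_gmt()`: `path`, invisibly. `read_gmt()`: a
#'   `geneset_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(t) {
    nm <- collection$names[[t]]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- t
    paste(c(nm, t, sort(collection$sets[[t]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param namespace namespace label to attach to the collection read back
#'   (GMT files do not record it).
#' @export
read_gmt <- function(path, namespace = "biological_process") {
  .assert_file_exists(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(new_geneset_collection(
      setNames(list(), character()), character(), .norm_namespace(namespace)
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 2L
  if (any(short)) {
    abort(sprintf("GMT parse error at line %d: fewer than 2 columns", which(short)[1L]))
  }
  set_names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(set_names)) {
    abort(sprintf("duplicate set name in GMT: %s", set_names[duplicated(set_names)][1L]))
  }
  descriptions <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(x) unique(x[-(1:2)]))
  # key by the accession in the description column when present
  key <- ifelse(is_go_accession(descriptions), descriptions, set_names)
  if (anyDuplicated(key)) {
    abort("duplicate set keys in GMT")
  }
  ord <- order(key)
  new_geneset_collection(
    setNames(genes[ord], key[ord]),
    setNames(set_names[ord], key[ord]),
    .norm_namespace(namespace),
    metadata = list(source = path)
  )
}

#' Effective gene-set size
#'
#' The number of a set's genes present in an expression dataset's gene
#' universe — the size on which inclusion bounds for enrichment analysis are
#' evaluated.
#'
#' @param genes character vector of a set's gene symbols.
#' @param universe character vector of gene symbols measured in the dataset.
#' @return integer count.
#' @export
effective_size <- function(genes, universe) {
  length(intersect(.norm_symbol(genes), .norm_symbol(universe)))
}

#' Filter a collection by effective size
#'
#' Keeps sets whose effective size (within `universe`) lies in
#' `[min_size, max_size]`, both bounds inclusive. The defaults (7 and 150)
#' are the conventional analysis bounds: below about 7 genes permutation
#' p-values lack granularity, and sets beyond about 150 genes are broad
#' high-level categories. `max_size = NULL` applies only the minimum
#' (release mode); `min_size = NULL` disables that bound too.
#'
#' @param collection a `geneset_collection`.
#' @param universe gene symbols defining effective size; `NULL` uses each
#'   set's full size.
#' @param min_size minimum effective size (inclusive), default 7.
#' @param max_size maximum effective size (inclusive), default 150.
#' @return filtered `geneset_collection`.
#' @export
size_filter <- function(collection, universe = NULL, min_size = 7, max_size = 150) {
  if (!is.null(min_size) && !is.null(max_size) && min_size > max_size) {
    abort("min_size must be <= max_size")
  }
  sizes <- if (is.null(universe)) {
    lengths(collection$sets)
  } else {
    u <- .norm_symbol(universe)
    vapply(collection$sets, function(g) length(intersect(.norm_symbol(g), u)), integer(1))
  }
  keep <- rep(TRUE, length(sizes))
  if (!is.null(min_size)) keep <- keep & sizes >= min_size
  if (!is.null(max_size)) keep <- keep & sizes <= max_size
  new_geneset_collection(
    collection$sets[keep], collection$names[names(collection$sets)[keep]],
    collection$namespace, collection$metadata
  )
}
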