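# In-code fixtures and independent oracles shared across the suite.

# --- tiny ontologies ---------------------------------------------------------

obo_file <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

term_stanza <- function(id, name = "a term", ns = "biological_process",
                        is_a = character(), part_of = character(),
                        extra = character()) {
  c(
    "[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    paste0("namespace: ", ns),
    if (length(is_a)) paste0("is_a: ", is_a),
    if (length(part_of)) paste0("relationship: part_of ", part_of),
    extra,
    ""
  )
}

# chain: A is_a B, B part_of C
chain_onto <- function() {
  parse_obo(obo_file(c(
    term_stanza("GO:0000003", "C"),
    term_stanza("GO:0000002", "B", part_of = "GO:0000003"),
    term_stanza("GO:0000001", "A", is_a = "GO:0000002")
  )))
}

# diamond: A -> B, A -> C, B -> D, C -> D
diamond_onto <- function() {
  parse_obo(obo_file(c(
    term_stanza("GO:0000004", "D"),
    term_stanza("GO:0000002", "B", is_a = "GO:0000004"),
    term_stanza("GO:0000003", "C", part_of = "GO:0000004"),
    term_stanza("GO:0000001", "A", is_a = c("GO:0000002", "GO:0000003"))
  )))
}

# --- annotation records ------------------------------------------------------

make_record <- function(symbol, term_id, evidence = "IDA",
                        qualifiers = character(), provenance = "BASELINE",
                        object_id = symbol, reference = "PMID:1",
                        taxon = "taxon:10090", db = "MGI") {
  tibble::tibble(
    db = db, object_id = object_id, symbol = symbol,
    qualifiers = list(qualifiers), term_id = term_id,
    references = reference, evidence_code = evidence, with_from = "",
    aspect = "P", object_name = "", synonym = "", object_type = "gene",
    taxon = taxon, date = "20130410", assigned_by = db,
    annotation_extension = "", gene_product_form_id = "",
    provenance = provenance, provenances = list(provenance)
  )
}

random_records <- function(n, seed, symbols = sprintf("G%02d", 1:8),
                           terms = sprintf("GO:%07d", 1:6)) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_record(
        symbol = sample(symbols, 1),
        term_id = sample(terms, 1),
        evidence = sample(c("IDA", "IMP", "IEA", "ISS", "TAS"), 1),
        qualifiers = if (stats::runif(1) < 0.2) "NOT" else character(),
        provenance = sample(c("BASELINE", "CURATED_ELIGIBLE", "CURATED_GONE", "ORTHOLOG"), 1),
        reference = sprintf("PMID:%d", sample.int(1e6, 1))
      )
    }))
  })
}

# --- independent oracles -----------------------------------------------------

# naive repeated-BFS transitive closure over an edges data frame
naive_closure <- function(edges, start, direction = c("up", "down")) {
  direction <- match.arg(direction)
  from <- if (direction == "up") edges$child else edges$parent
  to <- if (direction == "up") edges$parent else edges$child
  out <- character()
  frontier <- start
  repeat {
    nxt <- setdiff(unique(to[from %in% frontier]), out)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, start)
}

# brute-force running-sum enrichment score over every list position
brute_es <- function(scores, hit, weight) {
  N <- length(scores)
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  if (nr == 0) {
    w[] <- 1
    nr <- sum(w[hit])
  }
  miss <- 1 / (N - sum(hit))
  running <- 0
  best <- 0
  for (i in seq_len(N)) {
    running <- running + if (hit[i]) w[i] / nr else -miss
    # strict improvement beyond float noise; earlier extrema win ties
    if (abs(running) > abs(best) + 1e-9) best <- running
  }
  best
}

# one-sided Fisher p by explicit hypergeometric tail summation
enum_fisher <- function(sig_a, total_a, sig_b, total_b, direction) {
  k <- sig_a + sig_b
  tail_p <- function(x) {
    choose(total_a, x) * choose(total_b, k - x) / choose(total_a + total_b, k)
  }
  support <- max(0, k - total_b):min(k, total_a)
  if (direction == "a_greater") {
    sum(vapply(support[support >= sig_a], tail_p, 0))
  } else {
    sum(vapply(support[support <= sig_a], tail_p, 0))
  }
}

# naive gene-set construction: per gene, union term + ancestors, then invert
naive_build <- function(pairs, onto, namespace = "biological_process") {
  sets <- list()
  for (i in seq_len(nrow(pairs))) {
    terms <- c(pairs$term_id[i], naive_closure(onto$edges, pairs$term_id[i], "up"))
    for (t in terms) {
      sets[[t]] <- union(sets[[t]], toupper(pairs$symbol[i]))
    }
  }
  ns_terms <- onto$terms$term_id[onto$terms$namespace == namespace & !onto$terms$is_obsolete]
  sets <- sets[intersect(names(sets), ns_terms)]
  lapply(sets[order(names(sets))], sort)
}
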